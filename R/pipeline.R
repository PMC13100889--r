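#' Pipeline configuration
#'
#' Bundles every analysis parameter of a full multi-resolution run. The
#' scenario owns the data-generating conditions; the configuration owns the
#' analysis choices applied to them.
#'
#' @param scenario A scenario list (see [default_scenario()]), or `NULL` when
#'   `data` supplies a pre-built study.
#' @param levels Fine resolution levels to model (default: all fine levels of
#'   the hierarchy).
#' @param min_presences,reference_level Species inclusion filter (see
#'   [filter_species()]).
#' @param cap Training pseudoabsence cap per species.
#' @param frac_range Admissible held-out fraction range for the geographic
#'   holdout.
#' @param k Cross-validation folds.
#' @param n_perm Permutations per variable for importance.
#' @param members Registry member names to use (default: all nine).
#' @param priority Collinearity priority order; default prefers the
#'   conventionally retained set (bio1, bio7, minimum flow, roughness, land
#'   use, dam densities) before the neighbour variants.
#' @param collinearity_threshold Absolute Pearson cut for the screen.
#' @param neighbor_specs Data frame `(variable, direction)` of neighbour
#'   predictors to add before screening.
#' @param max_tries Restart budget for the holdout search.
#' @param seed Master seed; all stage seeds derive from it.
#' @param data Optional pre-built study: a list with `hierarchy`, `predictors`
#'   (finest level) and `records` (or an `occurrence_set`), bypassing the
#'   generators (real-data mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = default_scenario(), levels = NULL,
                            min_presences = 200, reference_level = NULL,
                            cap = 10000, frac_range = c(0.10, 0.30), k = 5,
                            n_perm = 10, members = names(learner_registry()),
                            priority = NULL, collinearity_threshold = 0.7,
                            neighbor_specs = default_neighbor_specs(),
                            max_tries = 200, seed = 1, data = NULL) {
  if (!is.numeric(frac_range) || length(frac_range) != 2 ||
      frac_range[1] <= 0 || frac_range[2] >= 1 ||
      frac_range[1] >= frac_range[2]) {
    stop_basinsdm("basinsdm_bad_argument",
                  "frac_range must satisfy 0 < min < max < 1")
  }
  structure(list(scenario = scenario, levels = levels,
                 min_presences = min_presences,
                 reference_level = reference_level, cap = cap,
                 frac_range = frac_range, k = k, n_perm = n_perm,
                 members = members, priority = priority,
                 collinearity_threshold = collinearity_threshold,
                 neighbor_specs = neighbor_specs, max_tries = max_tries,
                 seed = seed, data = data),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_neighbor_specs <- function() {
  tibble(variable = c("cropland", "builtup", "dam_density", "dam_density"),
         direction = c("upstream", "upstream", "upstream", "downstream"))
}

default_priority <- function(vars) {
  pref <- c("bio1", "bio7", "flow_min", "roughness", "cropland", "builtup",
            "dam_density", "cropland_up", "builtup_up", "dam_density_up",
            "dam_density_down")
  c(intersect(pref, vars), setdiff(vars, pref))
}

#' Run the full multi-resolution analysis
#'
#' Executes the complete workflow: simulate (or ingest) the study, aggregate
#' predictors to every modelled level, add neighbour predictors, screen
#' collinearity, clean occurrences and filter species, then per species and
#' level build the dataset (target-group pseudoabsences, geographic holdout,
#' folds), fit the nine-member ensemble, score it on the independent test
#' subset, compute permutation importance and the predicted/observed range
#' sizes, and finally compare TSS distributions across resolutions. A
#' failure in any species x level combination is caught, recorded in the
#' failure table with its context, and the run continues (per-species
#' isolation).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `basinsdm_run` with tibbles `evaluation` (species x level test
#'   TSS and thresholds), `member_tss`, `importance`, `ranges`, `screen`
#'   (collinearity report per level), `comparison` (Levene and
#'   repeated-measures ANOVA p-values), `failures`, and a reproducibility
#'   `manifest`. `status` is "success", "partial" (some species x level
#'   combinations failed) or "failed" (nothing completed).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  study <- if (is.null(config$data)) {
    say("simulating scenario '%s' (seed %d)",
        config$scenario$name %||% "unnamed", seed)
    simulate_scenario(config$scenario, seed)
  } else {
    config$data
  }
  h <- study$hierarchy
  fine_levels <- setdiff(h$levels, min(h$levels))
  levels <- config$levels %||% fine_levels
  ref_level <- config$reference_level %||% min(fine_levels)

  occ <- if (inherits(study$records, "occurrence_set")) {
    study$records
  } else {
    clean_occurrences(study$records, h,
                      window = study$scenario$window %||% c(1992L, 2015L))
  }
  species <- filter_species(occ, h, min_presences = config$min_presences,
                            reference_level = ref_level)
  say("%d species pass the %d-presence filter at level %d",
      length(species), config$min_presences, as.integer(ref_level))

  # per-level predictor preparation: aggregate, neighbours, collinearity
  registry <- learner_registry(config$members)
  tables <- list()
  screens <- list()
  retained <- list()
  for (lv in levels) {
    t_lv <- aggregate_to_level(study$predictors, h, lv)
    t_lv <- add_neighbor_predictors(t_lv, h, config$neighbor_specs)
    pri <- config$priority %||% default_priority(predictor_vars(t_lv))
    scr <- collinearity_filter(t_lv, threshold = config$collinearity_threshold,
                               priority = pri)
    tables[[as.character(lv)]] <- t_lv
    screens[[as.character(lv)]] <- scr$report |>
      mutate(level = as.integer(lv), .before = 1)
    retained[[as.character(lv)]] <- scr$retained
    say("level %d: %d basins, %d of %d predictors retained", as.integer(lv),
        nrow(t_lv$values), length(scr$retained),
        length(predictor_vars(t_lv)))
  }

  evaluation <- list()
  member_tss <- list()
  importance <- list()
  ranges <- list()
  failures <- list()
  for (sp in species) {
    for (lv in levels) {
      key <- paste(sp, lv)
      res <- tryCatch({
        t_lv <- tables[[as.character(lv)]]
        vars <- retained[[as.character(lv)]]
        ds <- build_species_dataset(occ, sp, lv, h, cap = config$cap,
                                    frac_range = config$frac_range,
                                    k = config$k, seed = seed,
                                    max_tries = config$max_tries)
        m <- fit_ensemble(ds, t_lv, vars, registry = registry, seed = seed)
        test <- independent_test_tss(m, ds, t_lv)
        train <- ds$data |> filter(.data$role == "train")
        imp <- permutation_importance(
          m, feature_matrix(t_lv, train$basin_id, vars),
          n_perm = config$n_perm,
          seed = derive_seed(seed, "importance", sp, lv))
        rng <- predict_range(m, t_lv, h, occ)
        list(
          evaluation = tibble(
            species_id = sp, level = as.integer(lv), test_tss = test$tss,
            test_threshold = test$threshold, train_tss = m$training_tss,
            threshold = m$threshold,
            n_train_presence = sum(train$label == 1),
            n_train_pseudoabsence = sum(train$label == 0),
            n_test = sum(ds$data$role == "test"),
            uninformative = m$uninformative),
          member_tss = tidy(m), importance = imp, ranges = rng)
      }, basinsdm_error = function(e) e)
      if (inherits(res, "error")) {
        say("  %s @ level %s failed: %s", sp, lv, conditionMessage(res))
        failures[[key]] <- tibble(
          species_id = sp, level = as.integer(lv),
          error = class(res)[1], message = conditionMessage(res))
      } else {
        say("  %s @ level %s: test TSS %.3f", sp, lv,
            res$evaluation$test_tss)
        evaluation[[key]] <- res$evaluation
        member_tss[[key]] <- res$member_tss
        importance[[key]] <- res$importance
        ranges[[key]] <- res$ranges
      }
    }
  }

  evaluation <- bind_rows(evaluation)
  comparison <- NULL
  if (nrow(evaluation)) {
    complete <- evaluation |>
      group_by(.data$species_id) |>
      filter(dplyr::n() == length(levels)) |>
      ungroup()
    if (dplyr::n_distinct(complete$species_id) >= 3 && length(levels) >= 2) {
      comparison <- compare_resolutions(
        complete |> select("species_id", "level", tss = "test_tss"))
    }
  }

  status <- if (!nrow(evaluation)) "failed"
            else if (length(failures)) "partial" else "success"
  manifest <- list(
    package_version = as.character(utils::packageVersion("basinsdm")),
    seed = seed, status = status,
    levels = as.integer(levels), species = species,
    scenario = if (is.null(config$data)) study$scenario else NULL,
    settings = config[c("min_presences", "cap", "frac_range", "k", "n_perm",
                        "members", "collinearity_threshold", "max_tries")],
    retained_vars = retained,
    counts = list(records = nrow(occ$records),
                  species_modelled = if (nrow(evaluation))
                    dplyr::n_distinct(evaluation$species_id) else 0L,
                  failures = length(failures)))
  structure(list(
    status = status, evaluation = evaluation,
    member_tss = bind_rows(member_tss), importance = bind_rows(importance),
    ranges = bind_rows(ranges), screen = bind_rows(screens),
    comparison = comparison, failures = bind_rows(failures),
    manifest = manifest, hierarchy = h, occurrences = occ,
    tables = tables), class = "basinsdm_run")
}

#' @export
print.basinsdm_run <- function(x, ...) {
  cat("<basinsdm_run> status: ", x$status, "\n", sep = "")
  cat(sprintf("  %d species x %d levels; %d combinations fitted, %d failed\n",
              length(x$manifest$species), length(x$manifest$levels),
              nrow(x$evaluation), nrow(x$failures)))
  if (nrow(x$evaluation)) {
    s <- x$evaluation |>
      group_by(.data$level) |>
      summarise(median_tss = median(.data$test_tss), .groups = "drop")
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  level %d: median test TSS %.3f\n", s$level[i],
                  s$median_tss[i]))
    }
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  Levene p = %.3f, repeated-measures ANOVA p = %.3f\n",
                x$comparison$levene_p, x$comparison$anova_p))
  }
  invisible(x)
}

#' @export
glance.basinsdm_run <- function(x, ...) {
  tibble(status = x$status,
         n_species = length(x$manifest$species),
         n_levels = length(x$manifest$levels),
         n_fitted = nrow(x$evaluation),
         n_failed = nrow(x$failures),
         median_test_tss = if (nrow(x$evaluation))
           median(x$evaluation$test_tss) else NA_real_,
         levene_p = if (!is.null(x$comparison)) x$comparison$levene_p
           else NA_real_,
         anova_p = if (!is.null(x$comparison)) x$comparison$anova_p
           else NA_real_)
}

#' Write a run's report files
#'
#' Writes the evaluation, member, importance, range and screening tables as
#' CSV and the manifest (plus the cross-resolution comparison) as JSON into
#' a directory, mirroring the package's external interfaces.
#'
#' @param run A `basinsdm_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(run$evaluation, file.path(dir, "evaluation.csv"))
  readr::write_csv(run$member_tss, file.path(dir, "member_tss.csv"))
  readr::write_csv(run$importance, file.path(dir, "importance.csv"))
  readr::write_csv(run$ranges |>
                     select(-"predicted_basins", -"observed_basins"),
                   file.path(dir, "ranges.csv"))
  readr::write_csv(run$screen, file.path(dir, "collinearity.csv"))
  if (nrow(run$failures)) {
    readr::write_csv(run$failures, file.path(dir, "failures.csv"))
  }
  jsonlite::write_json(
    c(run$manifest,
      list(comparison = if (!is.null(run$comparison))
        as.list(run$comparison) else NULL)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
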