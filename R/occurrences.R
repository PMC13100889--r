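#' Clean and deduplicate occurrence records
#'
#' Applies the standard archive-cleaning rules: records outside the year
#' window are dropped, records carrying an excluded quality flag are dropped,
#' records whose basin id does not resolve to a finest-level unit are dropped,
#' and the survivors are deduplicated to one observation per species per
#' finest-level basin (deduplication at coarser levels follows automatically
#' through ancestor mapping).
#'
#' @param raw Data frame of records with columns `species_id`, `basin_id`,
#'   `year`, and optionally `flags` (semicolon-separated issue codes).
#' @param h A [basin_hierarchy()]; records must reference its finest level.
#' @param window Length-2 integer vector of inclusive year bounds.
#' @param excluded_flags Character vector of issue codes that disqualify a
#'   record.
#' @return An `occurrence_set`: records tibble plus a `dropped` tibble of
#'   counts per reason (`window`, `flagged`, `no_basin`, `duplicate`).
#' @export
clean_occurrences <- function(raw, h, window = c(1992L, 2015L),
                              excluded_flags = character()) {
  raw <- as_tibble(raw)
  if (!all(c("species_id", "basin_id", "year") %in% names(raw))) {
    stop_basinsdm("basinsdm_bad_table",
                  "records need species_id, basin_id and year columns")
  }
  fine_ids <- basins_at_level(h, max(h$levels))$basin_id
  n0 <- nrow(raw)
  in_window <- !is.na(raw$year) & raw$year >= window[1] & raw$year <= window[2]
  step1 <- raw[in_window, ]
  flagged <- if ("flags" %in% names(step1) && length(excluded_flags)) {
    purrr::map_lgl(strsplit(tidyr::replace_na(step1$flags, ""), ";"),
                   ~ any(.x %in% excluded_flags))
  } else {
    rep(FALSE, nrow(step1))
  }
  step2 <- step1[!flagged, ]
  has_basin <- !is.na(step2$basin_id) & step2$basin_id %in% fine_ids
  step3 <- step2[has_basin, ]
  dedup <- step3 |>
    distinct(.data$species_id, .data$basin_id, .keep_all = TRUE) |>
    select("species_id", "basin_id", "year")
  dropped <- tibble(
    reason = c("window", "flagged", "no_basin", "duplicate"),
    n = c(n0 - nrow(step1), sum(flagged), sum(!has_basin),
          nrow(step3) - nrow(dedup)))
  structure(list(records = dedup, level = max(h$levels),
                 window = as.integer(window), dropped = dropped),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> ", nrow(x$records), " records, ",
      dplyr::n_distinct(x$records$species_id), " species, years ",
      x$window[1], "-", x$window[2], "\n", sep = "")
  invisible(x)
}

#' @export
tidy.occurrence_set <- function(x, ...) x$records

#' Presence basins of a species at a resolution level
#'
#' @param occ An `occurrence_set` from [clean_occurrences()].
#' @param h The [basin_hierarchy()].
#' @param species Species id.
#' @param level Modelled level.
#' @return Character vector of basin ids at `level` holding at least one
#'   record of the species.
#' @export
presences_at_level <- function(occ, h, species, level) {
  anc <- ancestor_map(h, occ$level, level)
  ids <- occ$records |>
    filter(.data$species_id == species) |>
    pull("basin_id")
  unique(unname(anc[ids]))
}

#' Target-group basins at a resolution level
#'
#' Basins holding at least one record of any species in the occurrence set:
#' the survey footprint shared by the species group, from which
#' pseudoabsences are drawn so background carries the same sampling bias as
#' the presences.
#'
#' @inheritParams presences_at_level
#' @return Character vector of basin ids at `level`.
#' @export
target_group_at_level <- function(occ, h, level) {
  anc <- ancestor_map(h, occ$level, level)
  unique(unname(anc[unique(occ$records$basin_id)]))
}

#' Select species with enough occurrences
#'
#' Retains species with at least `min_presences` presence basins at the
#' reference level (the coarsest fine level, conventionally level 8); the
#' bound is inclusive. The resulting list is reused at every modelled level.
#'
#' @inheritParams presences_at_level
#' @param min_presences Inclusive minimum presence count. Default 200, the
#'   conventional inclusion bound at level 8.
#' @param reference_level Level at which presences are counted.
#' @return Character vector of retained species ids (possibly empty, with a
#'   warning).
#' @export
filter_species <- function(occ, h, min_presences = 200,
                           reference_level = min(setdiff(h$levels, 4L))) {
  anc <- ancestor_map(h, occ$level, reference_level)
  counts <- occ$records |>
    mutate(ref = unname(anc[.data$basin_id])) |>
    distinct(.data$species_id, .data$ref) |>
    dplyr::count(.data$species_id)
  keep <- counts$species_id[counts$n >= min_presences]
  if (!length(keep)) {
    warn(sprintf("no species has >= %d presences at level %d",
                 min_presences, as.integer(reference_level)))
  }
  sort(keep)
}

#' Sample target-group pseudoabsences for a species
#'
#' The candidate pool contains the basins at `level` that (i) lie inside a
#' macro-basin (level 4) holding at least one focal presence, (ii) hold at
#' least one record of a different species (the target group), and (iii) hold
#' no focal record. If the pool exceeds `cap`, a uniform sample without
#' replacement of size `cap` is drawn.
#'
#' @inheritParams presences_at_level
#' @param cap Maximum number of pseudoabsences. Default 10,000, the
#'   conventional ceiling for ensemble SDMs.
#' @param seed Integer seed for the capped subsample.
#' @return Character vector of pseudoabsence basin ids.
#' @export
sample_pseudoabsences <- function(occ, species, level, h, cap = 10000,
                                  seed = 1) {
  pres <- presences_at_level(occ, h, species, level)
  if (!length(pres)) {
    stop_basinsdm("basinsdm_no_presences",
                  sprintf("species '%s' has no presences", species))
  }
  anc4 <- ancestor_map(h, level, 4L)
  occupied4 <- unique(unname(anc4[pres]))
  tg <- target_group_at_level(occ, h, level)
  pool <- setdiff(tg, pres)
  pool <- pool[unname(anc4[pool]) %in% occupied4]
  if (!length(pool)) {
    stop_basinsdm("basinsdm_empty_pool",
                  sprintf("no target-group pseudoabsence pool for '%s' at level %d",
                          species, as.integer(level)))
  }
  pool <- sort(pool)
  if (length(pool) <= cap) return(pool)
  with_seed(seed, sort(sample(pool, cap)))
}

#' Select macro-basins for the geographically independent test set
#'
#' Searches for a subset of occupied level-4 basins holding between
#' `frac_range[1]` and `frac_range[2]` of the presences AND of the
#' pseudoabsences. The search is randomized-greedy with restarts: shuffle the
#' candidate macro-basins, add them until the presence fraction enters the
#' range, accept if both class fractions qualify, otherwise reshuffle.
#'
#' @param presences,pseudoabsences Basin ids at `level` for the two classes.
#' @param h The [basin_hierarchy()].
#' @param level Level of the class records.
#' @param frac_range Admissible held-out fraction for both classes.
#' @param seed Integer seed.
#' @param max_tries Restart budget before giving up.
#' @return Character vector of held-out level-4 ids.
#' @export
select_test_basins <- function(presences, pseudoabsences, h, level,
                               frac_range = c(0.10, 0.30), seed = 1,
                               max_tries = 200) {
  anc4 <- ancestor_map(h, level, 4L)
  p4 <- unname(anc4[presences])
  a4 <- unname(anc4[pseudoabsences])
  cand <- sort(unique(p4))
  np <- length(presences)
  na <- length(pseudoabsences)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ord <- sample(cand)
      S <- character()
      fp <- 0
      for (b in ord) {
        S <- c(S, b)
        fp <- sum(p4 %in% S) / np
        if (fp >= frac_range[1]) break
      }
      fa <- sum(a4 %in% S) / na
      if (fp >= frac_range[1] && fp <= frac_range[2] &&
          fa >= frac_range[1] && fa <= frac_range[2]) {
        return(sort(S))
      }
    }
    stop_basinsdm(
      "basinsdm_no_holdout",
      sprintf(paste0("no level-4 holdout with both class fractions in ",
                     "[%.2f, %.2f] found in %d tries; consider relaxing ",
                     "the range"), frac_range[1], frac_range[2], max_tries))
  })
}

#' Assemble the modelling dataset for one species at one level
#'
#' Runs the full data-preparation chain: presences at the level, target-group
#' pseudoabsence pool (uncapped), geographically independent level-4 holdout,
#' pseudoabsence cap applied to the training pool, class-balancing weights,
#' and stratified cross-validation folds.
#'
#' Weights implement equal class weighting with the class-total convention:
#' presences weigh 1 and pseudoabsences weigh `n_presences /
#' n_pseudoabsences` within each role, so the summed weight of the two
#' classes is identical.
#'
#' @inheritParams presences_at_level
#' @param cap Training pseudoabsence cap (default 10,000).
#' @param frac_range Held-out fraction range for [select_test_basins()].
#' @param k Number of cross-validation folds.
#' @param seed Integer seed driving all stochastic steps.
#' @param max_tries Restart budget for the holdout search.
#' @return A `species_dataset`: `data` tibble `(basin_id, label, role,
#'   weight, fold)` plus the held-out level-4 ids.
#' @export
build_species_dataset <- function(occ, species, level, h, cap = 10000,
                                  frac_range = c(0.10, 0.30), k = 5,
                                  seed = 1, max_tries = 200) {
  pres <- presences_at_level(occ, h, species, level)
  pseu <- sample_pseudoabsences(occ, species, level, h, cap = Inf)
  test4 <- select_test_basins(pres, pseu, h, level, frac_range = frac_range,
                              seed = derive_seed(seed, "holdout", species,
                                                 level),
                              max_tries = max_tries)
  anc4 <- ancestor_map(h, level, 4L)
  d <- bind_rows(
    tibble(basin_id = pres, label = 1L),
    tibble(basin_id = pseu, label = 0L)
  ) |>
    mutate(role = ifelse(unname(anc4[.data$basin_id]) %in% test4,
                         "test", "train"))
  # cap applies to the training pool, after the geographic split
  train0 <- d |> filter(.data$role == "train", .data$label == 0L)
  if (nrow(train0) > cap) {
    keep <- with_seed(derive_seed(seed, "cap", species, level),
                      sample(train0$basin_id, cap))
    d <- d |> filter(.data$label == 1L | .data$role == "test" |
                       .data$basin_id %in% keep)
  }
  d <- d |>
    group_by(.data$role) |>
    mutate(weight = ifelse(.data$label == 1L, 1,
                           sum(.data$label == 1L) / sum(.data$label == 0L))) |>
    ungroup() |>
    mutate(fold = NA_integer_)
  ds <- structure(list(species_id = species, level = as.integer(level),
                       data = d, test_level4 = test4, k = as.integer(k),
                       seed = seed),
                  class = "species_dataset")
  assign_cv_folds(ds, k = k, seed = derive_seed(seed, "folds", species, level))
}

#' @export
print.species_dataset <- function(x, ...) {
  d <- x$data
  cat("<species_dataset> ", x$species_id, " at level ", x$level, "\n",
      sep = "")
  cat(sprintf("  train: %d presences, %d pseudoabsences (k = %d folds)\n",
              sum(d$label == 1 & d$role == "train"),
              sum(d$label == 0 & d$role == "train"), x$k))
  cat(sprintf("  test : %d presences, %d pseudoabsences in %d level-4 basins\n",
              sum(d$label == 1 & d$role == "test"),
              sum(d$label == 0 & d$role == "test"), length(x$test_level4)))
  invisible(x)
}

#' @export
tidy.species_dataset <- function(x, ...) x$data

#' Assign stratified cross-validation folds
#'
#' Partitions the training records into `k` folds stratified by class, so
#' each fold holds out `1/k` of the presences and `1/k` of the
#' pseudoabsences (within one record).
#'
#' @param dataset A `species_dataset`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return The dataset with the `fold` column filled for training records.
#' @export
assign_cv_folds <- function(dataset, k = 5, seed = 1) {
  d <- dataset$data
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(d$role == "train" & d$label == cls)
      if (length(idx) < k) {
        stop_basinsdm("basinsdm_too_few_records",
                      sprintf("class %d has fewer than %d training records",
                              cls, k))
      }
      d$fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  dataset$data <- d
  dataset$k <- as.integer(k)
  dataset
}
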