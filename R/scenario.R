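#' Simulation scenarios
#'
#' A scenario bundles every generator parameter: hierarchy shape, predictor
#' field specifications, the virtual species' niches, the sampling-effort
#' field and the detection model. `default_scenario()` is the package's
#' reference landscape: 10 macro-basins subdivided 75 x 2 x 2 into levels 8,
#' 9 and 10 (750 / 1,500 / 3,000 units, close to the unit-count ratios of
#' real nested-basin products), seven predictor families matching
#' the freshwater-fish predictor set, ten virtual species with
#' temperature-only Gaussian niches spanning the thermal gradient, and a
#' spatially autocorrelated effort field with a detection slope that records
#' roughly a third of the occupied basins -- sparse enough that observed
#' ranges fall well short of true occupancy at the finest level.
#' `demo_scenario()` is a five-macro-basin, eight-species miniature for
#' quick smoke runs.
#'
#' @return A list of generator parameters understood by
#'   [simulate_scenario()].
#' @export
default_scenario <- function() {
  list(
    name = "default",
    n_level4 = 10L,
    branching = c(75L, 2L, 2L),
    level4_median_km2 = 50364,
    area_sdlog = 0.4,
    predictor_vars = default_predictor_vars(),
    range_decay = 4,
    effort = list(range_decay = 6, sdlog = 0.8),
    detect_slope = 0.5,
    window = c(1992L, 2015L),
    species = lapply(seq_len(10), function(i) {
      list(species_id = sprintf("sp%02d", i),
           optima = list(bio1 = seq(8, 12, length.out = 10)[i]),
           breadths = list(bio1 = 4),
           max_prob = 0.95)
    })
  )
}

#' @rdname default_scenario
#' @export
demo_scenario <- function() {
  sc <- default_scenario()
  sc$name <- "demo"
  sc$n_level4 <- 5L
  sc$branching <- c(4L, 3L, 2L)
  sc$detect_slope <- 1.5
  sc$species <- lapply(seq_len(8), function(i) {
    list(species_id = sprintf("sp%02d", i),
         optima = list(bio1 = seq(6, 14, length.out = 8)[i]),
         breadths = list(bio1 = 5),
         max_prob = 0.95)
  })
  sc
}

#' Read or write a scenario as YAML
#'
#' One YAML file drives all the generators, so a simulated study is fully
#' described by (scenario file, seed).
#'
#' @param scenario A scenario list.
#' @param path YAML file path.
#' @return `read_scenario()` returns the scenario list; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  needed <- c("n_level4", "branching", "predictor_vars", "species",
              "detect_slope", "effort", "window", "range_decay")
  miss <- setdiff(needed, names(sc))
  if (length(miss)) {
    stop_basinsdm("basinsdm_bad_scenario",
                  paste0("scenario lacks fields: ", paste(miss, collapse = ", ")))
  }
  sc
}

#' Generate a full synthetic study from a scenario
#'
#' Runs every generator in sequence with seeds derived deterministically from
#' the master seed: hierarchy, predictor fields at the finest level, true
#' occupancy per species, the shared effort field, and biased occurrence
#' records. Identical (scenario, seed) pairs reproduce the study bit for
#' bit.
#'
#' @param scenario A scenario list (see [default_scenario()]).
#' @param seed Master integer seed.
#' @return A list with `hierarchy`, `predictors` (finest level), `truth`
#'   (per-species occupancy tibble), `effort`, `records` (occurrence tibble)
#'   and the scenario and seed used.
#' @export
simulate_scenario <- function(scenario, seed) {
  h <- sim_hierarchy(scenario$n_level4, scenario$branching,
                     seed = derive_seed(seed, "hierarchy"),
                     level4_median_km2 = scenario$level4_median_km2 %||% 50364,
                     area_sdlog = scenario$area_sdlog %||% 0.4)
  pt <- sim_predictors(h, vars = scenario$predictor_vars,
                       range_decay = scenario$range_decay,
                       seed = derive_seed(seed, "predictors"))
  effort <- sim_effort(h, range_decay = scenario$effort$range_decay,
                       sdlog = scenario$effort$sdlog,
                       seed = derive_seed(seed, "effort"))
  truth <- purrr::map(scenario$species, function(sp) {
    niche <- niche_spec(sp$species_id,
                        optima = unlist(sp$optima),
                        breadths = unlist(sp$breadths),
                        max_prob = sp$max_prob %||% 1,
                        prevalence_target = sp$prevalence_target)
    sim_species(h, pt, niche, seed = derive_seed(seed, "species",
                                                 sp$species_id))
  }) |> list_rbind()
  records <- sim_occurrences(truth, effort, scenario$detect_slope,
                             seed = derive_seed(seed, "occurrences"),
                             window = as.integer(scenario$window))
  list(hierarchy = h, predictors = pt, truth = truth, effort = effort,
       records = records, scenario = scenario, seed = seed)
}

#' Read and write occurrence record CSVs
#'
#' Plain CSV with columns `species_id, basin_id, year` (plus optional
#' `flags`).
#'
#' @param records Occurrence records tibble.
#' @param path CSV path.
#' @return `write_occurrences()` returns `path` invisibly;
#'   `read_occurrences()` returns a tibble.
#' @export
write_occurrences <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    basin_id = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_character()))
}
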