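# shared fixtures, built in code and memoised per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one macro-basin with two fine levels and hand-set areas / topology:
#   level 4: M (area 100)
#   level 8: A (60) -> B (40, outlet)
#   level 9: A1 (25) -> A2 (35, outlet of A's subtree), B1 (15) -> B2 (25)
tiny_hierarchy <- function() {
  basin_hierarchy(tibble::tibble(
    basin_id     = c("M", "A", "B", "A1", "A2", "B1", "B2"),
    level        = c(4L, 8L, 8L, 9L, 9L, 9L, 9L),
    parent_id    = c(NA, "M", "M", "A", "A", "B", "B"),
    next_down_id = c(NA, "B", NA, "A2", NA, "B2", NA),
    area         = c(100, 60, 40, 25, 35, 15, 25),
    cx           = c(0, -1, 1, -1.2, -0.8, 0.8, 1.2),
    cy           = c(0, 0, 0, 0.2, -0.2, 0.2, -0.2)))
}

tiny_predictors <- function(values) {
  # values: named list of level-9 vectors ordered A1, A2, B1, B2
  vals <- tibble::as_tibble(c(list(basin_id = c("A1", "A2", "B1", "B2")),
                              values))
  kinds <- vapply(names(values), function(v) {
    if (grepl("dam", v)) "density" else if (grepl("frac|crop|built", v))
      "fraction" else "mean"
  }, character(1))
  predictor_table(vals,
                  tibble::tibble(variable = names(values), kind = kinds,
                                 unit = "unit"),
                  level = 9L)
}

# a small simulated study reused across model-level tests
small_study <- function() {
  memo("small_study", simulate_scenario(demo_scenario(), seed = 402))
}

small_occ <- function() {
  memo("small_occ", {
    st <- small_study()
    clean_occurrences(st$records, st$hierarchy)
  })
}

# predictor table with neighbours at level 10 of the small study
small_table10 <- function() {
  memo("small_table10", {
    st <- small_study()
    add_neighbor_predictors(
      aggregate_to_level(st$predictors, st$hierarchy, 10),
      st$hierarchy, default_neighbor_specs())
  })
}

small_dataset <- function(species = "sp04") {
  memo(paste0("small_dataset_", species), {
    st <- small_study()
    build_species_dataset(small_occ(), species, 10, st$hierarchy,
                          seed = 402, max_tries = 500)
  })
}

# separable 1-d classification toy for learner-contract tests
toy_xy <- function(n = 200, seed = 1, sep = 2) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- data.frame(
      x1 = rnorm(n, mean = sep * y),
      x2 = rnorm(n))
    list(X = X, y = y, w = rep(1, n))
  })
}
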