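test_that("cleaning drops by window, flag and basin, and deduplicates", {
  h <- tiny_hierarchy()
  raw <- tibble::tibble(
    species_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    basin_id   = c("A1", "A1", "B1", "nowhere", "A2", "A2"),
    year       = c(2000L, 2005L, 1990L, 2000L, 2010L, 2010L),
    flags      = c("", "", "", "", "ZERO_COORDINATE", ""))
  occ <- clean_occurrences(raw, h, window = c(1992, 2015),
                           excluded_flags = "ZERO_COORDINATE")
  expect_equal(nrow(occ$records), 2) # s1@A1 (deduplicated), s2@A2
  d <- setNames(occ$dropped$n, occ$dropped$reason)
  expect_equal(d[["window"]], 1)    # the 1990 record
  expect_equal(d[["flagged"]], 1)
  expect_equal(d[["no_basin"]], 1)
  expect_equal(d[["duplicate"]], 1)
  # empty input: empty set, zero counts
  occ0 <- clean_occurrences(raw[0, ], h)
  expect_equal(nrow(occ0$records), 0)
  expect_true(all(occ0$dropped$n == 0))
})

test_that("deduplication never moves a record across macro-basins", {
  st <- small_study()
  occ <- small_occ()
  h <- st$hierarchy
  for (sp in c("sp02", "sp05")) {
    anc_fine <- vapply(presences_at_level(occ, h, sp, 10),
                       function(b) ancestor_at(h, b, 10, 4), character(1))
    anc_coarse <- vapply(presences_at_level(occ, h, sp, 8),
                         function(b) ancestor_at(h, b, 8, 4), character(1))
    expect_setequal(unique(anc_fine), unique(anc_coarse))
  }
})

test_that("the species filter applies an inclusive presence bound", {
  # 1 macro with 250 level-8 children; species with 199, 200, 201 presences
  n <- 250
  h <- basin_hierarchy(tibble::tibble(
    basin_id = c("M", sprintf("u%03d", 1:n)),
    level = c(4L, rep(8L, n)),
    parent_id = c(NA, rep("M", n)),
    next_down_id = NA_character_,
    area = c(n, rep(1, n))))
  raw <- dplyr::bind_rows(
    tibble::tibble(species_id = "just_under", basin_id = sprintf("u%03d", 1:199),
                   year = 2000L),
    tibble::tibble(species_id = "exactly", basin_id = sprintf("u%03d", 1:200),
                   year = 2000L),
    tibble::tibble(species_id = "over", basin_id = sprintf("u%03d", 1:201),
                   year = 2000L))
  occ <- clean_occurrences(raw, h)
  keep <- filter_species(occ, h, min_presences = 200, reference_level = 8)
  expect_setequal(keep, c("exactly", "over"))
  expect_warning(
    empty <- filter_species(occ, h, min_presences = 500, reference_level = 8))
  expect_length(empty, 0)
})

test_that("pseudoabsence pools match a brute-force triple filter", {
  st <- small_study()
  occ <- small_occ()
  h <- st$hierarchy
  level <- 10
  units <- basins_at_level(h, level)
  anc4 <- vapply(units$basin_id, function(b) ancestor_at(h, b, level, 4),
                 character(1))
  for (sp in c("sp01", "sp06")) {
    got <- sample_pseudoabsences(occ, sp, level, h, cap = Inf)
    # oracle: enumerate the three conditions independently per basin
    pres <- presences_at_level(occ, h, sp, level)
    occupied4 <- unique(anc4[pres])
    others <- lapply(setdiff(unique(occ$records$species_id), sp),
                     function(s) presences_at_level(occ, h, s, level))
    has_other <- units$basin_id %in% unique(unlist(others))
    expected <- units$basin_id[
      anc4[units$basin_id] %in% occupied4 &       # (i) inside occupied macros
        has_other &                               # (ii) target group, not focal
        !(units$basin_id %in% pres)]              # (iii) no focal record
    expect_setequal(got, expected)
  }
})

test_that("the pseudoabsence cap returns exactly cap records, reproducibly", {
  st <- small_study()
  occ <- small_occ()
  h <- st$hierarchy
  full <- sample_pseudoabsences(occ, "sp03", 10, h, cap = Inf)
  capped <- sample_pseudoabsences(occ, "sp03", 10, h, cap = 25, seed = 9)
  capped2 <- sample_pseudoabsences(occ, "sp03", 10, h, cap = 25, seed = 9)
  expect_length(capped, 25)
  expect_identical(capped, capped2)
  expect_true(all(capped %in% full))
})

test_that("an exhausted pseudoabsence pool raises a structured error", {
  h <- tiny_hierarchy()
  raw <- tibble::tibble(
    species_id = c("focal", "focal", "focal", "focal"),
    basin_id = c("A1", "A2", "B1", "B2"), year = 2000L)
  occ <- clean_occurrences(raw, h)
  err <- expect_error(sample_pseudoabsences(occ, "focal", 9, h),
                      class = "basinsdm_empty_pool")
  expect_match(conditionMessage(err), "focal")
})

test_that("holdout macro-basins carry the required share of both classes", {
  # 10 macro-basins each holding exactly 10% of presences and pseudoabsences
  n4 <- 10
  units <- list(tibble::tibble(
    basin_id = sprintf("M%02d", 1:n4), level = 4L, parent_id = NA_character_,
    next_down_id = NA_character_, area = 40))
  for (i in 1:n4) {
    units[[i + 1]] <- tibble::tibble(
      basin_id = sprintf("M%02d.%d", i, 1:8), level = 8L,
      parent_id = sprintf("M%02d", i), next_down_id = NA_character_, area = 5)
  }
  h <- basin_hierarchy(dplyr::bind_rows(units))
  pres <- sprintf("M%02d.%d", rep(1:n4, each = 2), rep(1:2, n4))
  pseu <- sprintf("M%02d.%d", rep(1:n4, each = 3), rep(3:5, n4))
  S <- select_test_basins(pres, pseu, h, 8, seed = 4)
  expect_length(S, 1) # any single macro holds exactly 10% of each class
  frac_p <- mean(vapply(pres, function(b) ancestor_at(h, b, 8, 4),
                        character(1)) %in% S)
  expect_true(frac_p >= 0.10 && frac_p <= 0.30)

  # skewed case: one macro holds 50% of presences and can never be chosen
  pres_sk <- c(sprintf("M01.%d", 1:8), sprintf("M%02d.1", 2:9))
  pseu_sk <- sprintf("M%02d.%d", rep(2:9, each = 2), rep(2:3, 8))
  S_sk <- select_test_basins(pres_sk, pseu_sk, h, 8, seed = 4,
                             max_tries = 500)
  expect_false("M01" %in% S_sk)
  fp <- mean(vapply(pres_sk, function(b) ancestor_at(h, b, 8, 4),
                    character(1)) %in% S_sk)
  fa <- mean(vapply(pseu_sk, function(b) ancestor_at(h, b, 8, 4),
                    character(1)) %in% S_sk)
  expect_true(fp >= 0.10 && fp <= 0.30)
  expect_true(fa >= 0.10 && fa <= 0.30)

  # impossible range: structured error advising relaxation
  expect_error(
    select_test_basins(pres, pseu, h, 8, frac_range = c(0.011, 0.012),
                       seed = 1, max_tries = 20),
    class = "basinsdm_no_holdout")
})

test_that("accepted holdouts verify post hoc over random instances", {
  st <- small_study()
  occ <- small_occ()
  h <- st$hierarchy
  for (seed in 1:5) {
    pres <- presences_at_level(occ, h, "sp04", 10)
    pseu <- sample_pseudoabsences(occ, "sp04", 10, h, cap = Inf)
    S <- select_test_basins(pres, pseu, h, 10, seed = seed, max_tries = 500)
    fp <- mean(vapply(pres, function(b) ancestor_at(h, b, 10, 4),
                      character(1)) %in% S)
    fa <- mean(vapply(pseu, function(b) ancestor_at(h, b, 10, 4),
                      character(1)) %in% S)
    expect_true(fp >= 0.10 && fp <= 0.30)
    expect_true(fa >= 0.10 && fa <= 0.30)
  }
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  ds <- small_dataset()
  d <- ds$data[ds$data$role == "train", ]
  expect_true(all(d$fold %in% 1:5))
  tab <- table(d$fold, d$label)
  # each fold holds 1/k of each class within one record
  for (cls in c("0", "1")) {
    expect_lte(diff(range(tab[, cls])), 1)
  }
  expect_equal(sum(tab), nrow(d))
})

test_that("species datasets respect class disjointness, weights and geography", {
  st <- small_study()
  ds <- small_dataset()
  d <- ds$data
  pres <- d$basin_id[d$label == 1]
  pseu <- d$basin_id[d$label == 0]
  expect_length(intersect(pres, pseu), 0)
  # equal class weighting within each role
  for (r in c("train", "test")) {
    dr <- d[d$role == r, ]
    expect_equal(sum(dr$weight[dr$label == 1]),
                 sum(dr$weight[dr$label == 0]), tolerance = 1e-12)
  }
  # each macro-basin is wholly in train or wholly in test
  anc <- vapply(d$basin_id,
                function(b) ancestor_at(st$hierarchy, b, ds$level, 4),
                character(1))
  split_roles <- tapply(d$role, anc, function(x) length(unique(x)))
  expect_true(all(split_roles == 1))
  expect_true(all(unique(anc[d$role == "test"]) %in% ds$test_level4))
  # reproducibility
  ds2 <- build_species_dataset(small_occ(), ds$species_id, 10, st$hierarchy,
                               seed = 402, max_tries = 500)
  expect_identical(ds$data, ds2$data)
})

test_that("occurrence records round-trip through CSV", {
  st <- small_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(st$records, path)
  rec <- read_occurrences(path)
  expect_equal(as.data.frame(rec), as.data.frame(st$records))
})
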