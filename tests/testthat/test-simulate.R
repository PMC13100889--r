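test_that("hierarchy generator produces the configured unit counts", {
  h <- sim_hierarchy(n_level4 = 2, branching = c(4, 2, 2), seed = 1)
  counts <- dplyr::count(tidy(h), level)
  expect_equal(counts$n, c(2, 8, 16, 32))
  expect_equal(basin_levels(h), c(4L, 8L, 9L, 10L))
})

test_that("generated areas partition parents and seeds reproduce exactly", {
  h1 <- sim_hierarchy(3, c(4, 3), seed = 42)
  h2 <- sim_hierarchy(3, c(4, 3), seed = 42)
  h3 <- sim_hierarchy(3, c(4, 3), seed = 43)
  expect_identical(tidy(h1), tidy(h2))
  expect_false(identical(tidy(h1)$area, tidy(h3)$area))
  # construction already validates child-area sums; check one level directly
  kids <- basins_at_level(h1, 8) |>
    dplyr::group_by(parent_id) |>
    dplyr::summarise(s = sum(area))
  parents <- basins_at_level(h1, 4)
  expect_equal(kids$s[match(parents$basin_id, kids$parent_id)], parents$area,
               tolerance = 1e-12)
})

test_that("predictor fields respect their kinds and determinism", {
  h <- sim_hierarchy(2, c(4, 3), seed = 2)
  pt <- sim_predictors(h, seed = 5)
  pt2 <- sim_predictors(h, seed = 5)
  expect_identical(pt$values, pt2$values)
  expect_true(all(pt$values$cropland >= 0 & pt$values$cropland <= 1))
  expect_true(all(pt$values$builtup >= 0 & pt$values$builtup <= 1))
  expect_true(all(pt$values$dam_density >= 0))
})

test_that("an effectively infinite length scale collapses between-basin variance", {
  h <- sim_hierarchy(2, c(5, 3), seed = 3)
  v_short <- var(sim_predictors(h, range_decay = 0.1, seed = 9)$values$bio1)
  v_long <- var(sim_predictors(h, range_decay = 1e6, seed = 9)$values$bio1)
  expect_lt(v_long, v_short / 10)
})

test_that("the empirical variogram tightens as the length scale grows", {
  h <- sim_hierarchy(2, c(5, 3), seed = 4)
  fine <- basins_at_level(h, 9)
  d <- as.matrix(dist(cbind(fine$cx, fine$cy)))
  near <- d > 0 & d < median(d[d > 0]) / 2 # short-lag pairs
  semiv <- function(ls, rep_seed) {
    z <- sim_predictors(
      h, vars = list(list(name = "bio1", kind = "mean", unit = "degC",
                          mu = 0, sigma = 1, log = FALSE)),
      range_decay = ls, seed = rep_seed)$values$bio1
    dif <- outer(z, z, "-")^2
    mean(dif[near]) / 2
  }
  scales <- c(0.5, 2, 8)
  means <- vapply(scales, function(ls) {
    mean(vapply(1:50, function(r) semiv(ls, 1000 + r), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0)) # monotone decrease over the 3 scales
})

test_that("niche responses follow the Gaussian closed form", {
  h <- tiny_hierarchy()
  pt <- tiny_predictors(list(bio1 = c(10, 10 + 3 * 2, 12, 8)))
  sp <- sim_species(h, pt, niche_spec("v", c(bio1 = 10), c(bio1 = 2),
                                      max_prob = 1), seed = 1)
  expect_equal(sp$prob[1], 1)                   # at the optimum
  expect_equal(sp$prob[2], exp(-4.5))           # three breadths away
  expect_equal(sp$prob[3], exp(-(2^2) / (2 * 4)))
  expect_error(
    sim_species(h, pt, niche_spec("v", c(nope = 1), c(nope = 1)), seed = 1),
    class = "basinsdm_missing_predictor")
})

test_that("realised prevalence matches mean probability at large n", {
  h <- sim_hierarchy(1, c(50, 100), seed = 6) # 5,000 finest units
  fine <- basins_at_level(h, 9)
  pt <- predictor_table(
    tibble::tibble(basin_id = fine$basin_id,
                   bio1 = withr::with_seed(1, rnorm(nrow(fine), 10, 4))),
    tibble::tibble(variable = "bio1", kind = "mean", unit = "degC"),
    level = 9L)
  sp <- sim_species(h, pt, niche_spec("v", c(bio1 = 10), c(bio1 = 4),
                                      max_prob = 0.9), seed = 11)
  p_mean <- mean(sp$prob)
  se <- sqrt(p_mean * (1 - p_mean) / nrow(sp))
  expect_lt(abs(mean(sp$occupied) - p_mean), 4 * se)
})

test_that("detection thins presences according to the effort model", {
  h <- sim_hierarchy(1, c(40, 30), seed = 7) # 1,200 finest units
  fine <- basins_at_level(h, 9)
  truth <- tibble::tibble(species_id = "v", basin_id = fine$basin_id,
                          prob = 1, occupied = TRUE)
  # zero effort: no records at all
  eff0 <- tibble::tibble(basin_id = fine$basin_id, effort = 0)
  expect_equal(nrow(sim_occurrences(truth, eff0, 1, seed = 1)), 0)
  # saturating detection recovers true occupancy exactly
  eff1 <- tibble::tibble(basin_id = fine$basin_id, effort = 1)
  rec <- sim_occurrences(truth, eff1, 1e9, seed = 1)
  expect_setequal(rec$basin_id, fine$basin_id)
  # detection fraction matches 1 - exp(-slope * effort) at constant effort
  slope <- 0.7
  rec2 <- sim_occurrences(truth, eff1, slope, seed = 2)
  p <- 1 - exp(-slope)
  se <- sqrt(p * (1 - p) / nrow(fine))
  expect_lt(abs(nrow(rec2) / nrow(fine) - p), 4 * se)
  expect_true(all(rec2$year >= 1992 & rec2$year <= 2015))
})

test_that("a whole simulated study is reproducible bit for bit", {
  sc <- demo_scenario()
  s1 <- simulate_scenario(sc, seed = 88)
  s2 <- simulate_scenario(sc, seed = 88)
  expect_identical(tidy(s1$hierarchy), tidy(s2$hierarchy))
  expect_identical(s1$predictors$values, s2$predictors$values)
  expect_identical(s1$records, s2$records)
})

test_that("scenarios survive the YAML round trip", {
  sc <- demo_scenario()
  path <- withr::local_tempfile(fileext = ".yml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  s1 <- simulate_scenario(sc, seed = 5)
  s2 <- simulate_scenario(sc2, seed = 5)
  expect_identical(s1$records, s2$records)
})
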