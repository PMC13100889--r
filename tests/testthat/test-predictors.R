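test_that("aggregation takes area-weighted means, fractions and densities", {
  h <- tiny_hierarchy()
  # A1 (25) and A2 (35) under A; B1 (15) and B2 (25) under B
  pt <- tiny_predictors(list(
    temp = c(10, 20, 10, 20),
    crop_frac = c(0.2, 0.2, 0.2, 0.6),
    dam_density = c(3 / 25, 3 / 25, 3 / 15, 1 / 25)))
  agg <- aggregate_to_level(pt, h, 8)
  v <- agg$values[match(c("A", "B"), agg$values$basin_id), ]
  expect_equal(v$temp[1], (10 * 25 + 20 * 35) / 60)
  # equal-fraction children give that fraction back
  expect_equal(v$crop_frac[1], 0.2)
  # fractions 0.2 over 15 km2 and 0.6 over 25 km2
  expect_equal(v$crop_frac[2], (0.2 * 15 + 0.6 * 25) / 40)
  # dam counts 3 and 1 over areas 15 and 25: density 4/40
  expect_equal(v$dam_density[2], 4 / 40)
  expect_error(aggregate_to_level(agg, h, 9), class = "basinsdm_bad_argument")
  expect_identical(aggregate_to_level(pt, h, 9), pt) # identity at own level
})

test_that("worked aggregation examples give the closed-form values", {
  # two equal-area children valued 10 and 20 aggregate to 15;
  # fractions 0.2 (area 75) and 0.6 (area 25) aggregate to 0.3;
  # dam counts 3 and 1 over areas 50 and 150 give density 0.02
  h <- basin_hierarchy(tibble::tibble(
    basin_id = c("P", "c1", "c2", "Q", "d1", "d2", "R", "e1", "e2"),
    level = c(4L, 8L, 8L, 4L, 8L, 8L, 4L, 8L, 8L),
    parent_id = c(NA, "P", "P", NA, "Q", "Q", NA, "R", "R"),
    next_down_id = NA_character_,
    area = c(20, 10, 10, 100, 75, 25, 200, 50, 150)))
  pt <- predictor_table(
    tibble::tibble(basin_id = c("c1", "c2", "d1", "d2", "e1", "e2"),
                   temp = c(10, 20, 0, 0, 0, 0),
                   crop = c(0, 0, 0.2, 0.6, 0, 0),
                   dams = c(0, 0, 0, 0, 3 / 50, 1 / 150)),
    tibble::tibble(variable = c("temp", "crop", "dams"),
                   kind = c("mean", "fraction", "density"), unit = "u"),
    level = 8L)
  agg <- aggregate_to_level(pt, h, 4)
  v <- agg$values[match(c("P", "Q", "R"), agg$values$basin_id), ]
  expect_equal(v$temp[1], 15)
  expect_equal(v$crop[2], 0.3)
  expect_equal(v$dams[3], 4 / 200)
})

test_that("aggregation conserves area-weighted totals and dam counts", {
  h <- sim_hierarchy(3, c(5, 3, 2), seed = 12)
  pt <- sim_predictors(h, seed = 13)
  areas10 <- basins_at_level(h, 10)
  for (lv in c(4L, 8L, 9L)) {
    agg <- aggregate_to_level(pt, h, lv)
    areas <- basins_at_level(h, lv)
    a <- agg$values |> dplyr::left_join(areas, by = "basin_id")
    f <- pt$values |> dplyr::left_join(areas10, by = "basin_id")
    for (v in c("bio1", "cropland", "dam_density")) {
      expect_equal(sum(a[[v]] * a$area), sum(f[[v]] * f$area),
                   tolerance = 1e-9)
    }
  }
})

test_that("neighbour predictors propagate one-step up- and downstream", {
  h <- tiny_hierarchy()
  pt <- tiny_predictors(list(dam_density = c(0.02, 0.04, 0.1, 0.3)))
  # level-9 topology: A1 -> A2, B1 -> B2 (A2, B2 outlets)
  out <- add_neighbor_predictors(
    pt, h, tibble::tibble(variable = "dam_density",
                          direction = c("upstream", "downstream")))
  v <- out$values[match(c("A1", "A2", "B1", "B2"), out$values$basin_id), ]
  expect_equal(v$dam_density_up, c(0, 0.02, 0, 0.1))   # headwaters get 0
  expect_equal(v$dam_density_down, c(0.04, 0, 0.3, 0)) # outlets get 0
  # confluence: two tributaries into one unit average their values
  h8 <- basin_hierarchy(tibble::tibble(
    basin_id = c("M", "X", "T1", "T2"), level = c(4L, 8L, 8L, 8L),
    parent_id = c(NA, "M", "M", "M"),
    next_down_id = c(NA, NA, "X", "X"), area = c(30, 10, 10, 10)))
  p8 <- predictor_table(
    tibble::tibble(basin_id = c("X", "T1", "T2"), dams = c(0, 0.02, 0.04)),
    tibble::tibble(variable = "dams", kind = "density", unit = "u"), 8L)
  o8 <- add_neighbor_predictors(
    p8, h8, tibble::tibble(variable = "dams", direction = "upstream"))
  expect_equal(o8$values$dams_up[o8$values$basin_id == "X"], 0.03)
})

test_that("collinearity screen drops the lower-priority member of each pair", {
  n <- 60
  x <- withr::with_seed(30, rnorm(n))
  noise <- withr::with_seed(31, rnorm(n))
  tab <- tibble::tibble(
    basin_id = as.character(seq_len(n)),
    bio1 = x,
    bio5 = 2 * x + 1,          # |r| = 1 with bio1
    bio10 = -3 * x,            # |r| = 1 with bio1
    roughness = noise,         # independent
    flat = rep(1, n))          # zero variance
  res <- collinearity_filter(tab, threshold = 0.7,
                             priority = c("bio1", "bio5", "bio10",
                                          "roughness"))
  expect_setequal(res$retained, c("bio1", "roughness"))
  drops <- res$report[res$report$action == "dropped", ]
  expect_setequal(drops$variable, c("bio5", "bio10"))
  expect_true(all(drops$partner == "bio1"))
  expect_true(all(abs(drops$r) >= 0.7))
  expect_equal(res$report$action[res$report$variable == "flat"],
               "zero_variance")
  # all pairwise |r| below the threshold in the retained set
  expect_lt(abs(cor(tab$bio1, tab$roughness)), 0.7)
  # order stability: identical inputs give identical output
  res2 <- collinearity_filter(tab, threshold = 0.7,
                              priority = c("bio1", "bio5", "bio10",
                                           "roughness"))
  expect_identical(res, res2)
})

test_that("orthogonal variables are all retained", {
  tab <- tibble::tibble(basin_id = as.character(1:4),
                        a = c(1, 1, -1, -1), b = c(1, -1, 1, -1),
                        c = c(1, -1, -1, 1)) # mutually orthogonal
  res <- collinearity_filter(tab, threshold = 0.7)
  expect_setequal(res$retained, c("a", "b", "c"))
})

test_that("variance decomposition satisfies the total-SS identity", {
  h <- tiny_hierarchy()
  # constant within each level-8 group: no within-group variance
  ptc <- tiny_predictors(list(v = c(5, 5, 9, 9)))
  d <- variance_decomposition(ptc, h, 8, "v")
  expect_equal(d$ss_within, 0)
  expect_equal(d$prop_between, 1)
  # all identical: degenerate, flagged
  pti <- tiny_predictors(list(v = rep(3, 4)))
  di <- variance_decomposition(pti, h, 8, "v")
  expect_true(di$degenerate)
  expect_equal(di$ss_between + di$ss_within, 0)
  # random values: ss_between + ss_within equals total SS (brute force)
  hq <- sim_hierarchy(3, c(4, 3), seed = 17)
  pq <- sim_predictors(hq, seed = 18)
  for (v in c("bio1", "cropland")) {
    dd <- variance_decomposition(pq, hq, 8, v)
    x <- pq$values[[v]]
    expect_equal(dd$ss_between + dd$ss_within, sum((x - mean(x))^2),
                 tolerance = 1e-9)
    expect_equal(dd$prop_between + dd$prop_within, 1, tolerance = 1e-12)
  }
})

test_that("predictor tables round-trip through CSV plus YAML schema", {
  h <- sim_hierarchy(2, c(3, 2), seed = 19)
  pt <- sim_predictors(h, seed = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictor_table(pt, path)
  pt2 <- read_predictor_table(path)
  expect_equal(pt$level, pt2$level)
  expect_equal(pt$schema, pt2$schema)
  expect_equal(as.data.frame(pt$values), as.data.frame(pt2$values),
               tolerance = 1e-12)
})
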