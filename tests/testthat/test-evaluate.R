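test_that("TSS reproduces its closed-form values and rejects empty classes", {
  expect_equal(tss(tp = 50, fn = 0, tn = 50, fp = 0), 1.0)
  expect_equal(tss(tp = 0, fn = 50, tn = 0, fp = 50), -1.0)
  expect_equal(tss(tp = 40, fn = 10, tn = 30, fp = 20), 0.4)
  expect_error(tss(tp = 0, fn = 0, tn = 10, fp = 5),
               class = "basinsdm_single_class")
  expect_error(tss(tp = -1, fn = 1, tn = 1, fp = 1),
               class = "basinsdm_bad_argument")
})

test_that("TSS is invariant to duplicating every record", {
  for (k in c(2, 5)) {
    expect_equal(tss(40 * k, 10 * k, 30 * k, 20 * k), tss(40, 10, 30, 20))
  }
})

test_that("threshold optimisation finds the exact maximum and breaks ties low", {
  # perfectly separated: max TSS 1 at the smallest separating threshold
  y <- c(1, 1, 0, 0)
  poo <- c(0.9, 0.9, 0.1, 0.1)
  opt <- max_tss_threshold(y, poo)
  expect_equal(opt$tss, 1)
  expect_equal(opt$threshold, 0.9)
  expect_equal(unname(opt$counts), c(2L, 0L, 2L, 0L))
  # constant predictions: no skill, but never below zero
  flat <- max_tss_threshold(y, rep(0.5, 4))
  expect_equal(flat$tss, 0)
  expect_error(max_tss_threshold(c(1, 1), c(0.4, 0.6)),
               class = "basinsdm_single_class")
})

test_that("unique-value scan agrees with a fine fixed-grid scan", {
  for (i in 1:100) {
    inst <- withr::with_seed(2000 + i, {
      n <- 40
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      # probabilities on the grid's resolution so both scans see the optimum
      list(y = y, poo = round(runif(n), 3))
    })
    exact <- max_tss_threshold(inst$y, inst$poo)
    grid <- max_tss_threshold(inst$y, inst$poo, grid = 0.001)
    expect_equal(exact$tss, grid$tss, tolerance = 1e-12)
    expect_gte(exact$tss, 0)
  }
})

test_that("independent-test evaluation matches training on a memorised set and errors on one class", {
  st <- small_study()
  ds <- small_dataset()
  t10 <- small_table10()
  vars <- c("bio1", "bio7", "roughness")
  m <- fit_ensemble(ds, t10, vars, registry = learner_registry("RF"),
                    seed = 77)
  # score the model back on its own training rows via a pseudo-test dataset
  ds_mem <- ds
  ds_mem$data <- ds$data |>
    dplyr::filter(role == "train") |>
    dplyr::mutate(role = "test")
  mem <- independent_test_tss(m, ds_mem, t10)
  expect_gte(mem$tss, m$training_tss - 0.05) # memorising learner, same rows
  # a single-class test subset is undefined
  ds_one <- ds
  ds_one$data <- ds$data |> dplyr::filter(label == 1)
  expect_error(independent_test_tss(m, ds_one, t10),
               class = "basinsdm_single_class")
  # the reuse-threshold mode scores at the training threshold
  reused <- independent_test_tss(m, ds, t10, reuse_threshold = TRUE)
  expect_equal(reused$threshold, m$threshold)
  expect_lte(reused$tss, independent_test_tss(m, ds, t10)$tss + 1e-12)
})

test_that("permuting an ignored variable yields exactly zero importance", {
  toy <- toy_xy(n = 150, seed = 41)
  fit <- fit_learner(learner_spec("GLM"), toy$X["x1"], toy$y, toy$w)
  m <- build_ensemble(list(GLM = fit), c(GLM = 0.8), toy$X["x1"], toy$y)
  X <- cbind(toy$X, junk = rnorm(150))
  imp <- permutation_importance(m, X, variables = c("x1", "junk"),
                                n_perm = 5, seed = 3)
  expect_equal(imp$importance[imp$variable == "junk"], 0)
  expect_gt(imp$importance[imp$variable == "x1"], 0)
})

test_that("permutation importance is high for the sole informative variable", {
  n <- 1000
  toy <- withr::with_seed(43, {
    y <- rep(c(0L, 1L), each = n / 2)
    list(X = data.frame(x1 = rnorm(n, 3 * y), x2 = rnorm(n)),
         y = y, w = rep(1, n))
  })
  fit <- fit_learner(learner_spec("GLM"), toy$X, toy$y, toy$w)
  m <- build_ensemble(list(GLM = fit), c(GLM = 0.9), toy$X, toy$y)
  imp <- permutation_importance(m, toy$X, n_perm = 10, seed = 5)
  expect_gt(imp$importance[imp$variable == "x1"], 0.5)
  expect_lt(imp$importance[imp$variable == "x2"],
            imp$importance[imp$variable == "x1"])
  # reproducible under a fixed seed
  imp2 <- permutation_importance(m, toy$X, n_perm = 10, seed = 5)
  expect_identical(imp, imp2)
})

test_that("cross-resolution comparison behaves at its boundaries and under shifts", {
  # identical TSS columns across levels: F = 0, boundary p = 1
  base <- withr::with_seed(61, runif(30, 0.2, 0.6))
  flat <- tidyr::expand_grid(species_id = sprintf("s%02d", 1:30),
                             level = 8:12) |>
    dplyr::mutate(tss = rep(base, each = 5))
  cmp <- compare_resolutions(flat)
  expect_equal(cmp$anova_p, 1)
  # one level shifted by +0.3 with sd 0.05 across 49 species
  shifted <- withr::with_seed(62, {
    tidyr::expand_grid(species_id = sprintf("s%02d", 1:49), level = 8:12) |>
      dplyr::mutate(tss = rnorm(dplyr::n(), 0.4, 0.05) +
                      ifelse(level == 10, 0.3, 0))
  })
  expect_lt(compare_resolutions(shifted)$anova_p, 0.01)
  # heteroscedastic construction: one level's spread inflated fivefold
  hetero <- withr::with_seed(63, {
    tidyr::expand_grid(species_id = sprintf("s%02d", 1:49), level = 8:12) |>
      dplyr::mutate(tss = rnorm(dplyr::n(), 0.4,
                                ifelse(level == 12, 0.25, 0.05)))
  })
  expect_lt(compare_resolutions(hetero)$levene_p, 0.05)
  # unbalanced input is rejected
  expect_error(compare_resolutions(flat[-1, ]), class = "basinsdm_bad_table")
})
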