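#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`,
#' ranging from -1 to +1 (perfect prediction), with 0 the skill of a random
#' assignment. Unlike prevalence-sensitive scores it penalises false
#' presences and false absences symmetrically.
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts. Both classes must be
#'   represented (`tp + fn >= 1` and `tn + fp >= 1`).
#' @return The TSS as a single number.
#' @export
#' @examples
#' tss(tp = 40, fn = 10, tn = 30, fp = 20) # 0.8 + 0.6 - 1 = 0.4
tss <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_basinsdm("basinsdm_bad_argument", "confusion counts must be >= 0")
  }
  if (tp + fn < 1 || tn + fp < 1) {
    stop_basinsdm("basinsdm_single_class",
                  "TSS undefined: one class has no records")
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Threshold maximising the TSS
#'
#' Scans every candidate threshold -- the sorted unique predicted values plus
#' 0 and 1 -- under the rule `poo >= threshold` implies presence, and returns
#' the smallest threshold attaining the maximal TSS (ties broken toward
#' larger predicted ranges). Because threshold 0 (predict everything present)
#' is always a candidate, the maximum is never below 0. An optional
#' fixed-grid mode reproduces platform-style scanning on an even grid.
#'
#' @param y Binary labels (0/1) with both classes present.
#' @param poo Predicted probabilities of occurrence in `[0, 1]`.
#' @param grid Optional step size (e.g. `0.001`) to scan a fixed grid
#'   instead of the unique predicted values.
#' @return List with `threshold`, `tss`, and the confusion `counts`
#'   (`tp`, `fn`, `tn`, `fp`) at the optimum.
#' @export
max_tss_threshold <- function(y, poo, grid = NULL) {
  y <- as.integer(y)
  if (length(y) != length(poo)) {
    stop_basinsdm("basinsdm_bad_argument", "y and poo lengths differ")
  }
  P <- sum(y == 1)
  N <- sum(y == 0)
  if (P < 1 || N < 1) {
    stop_basinsdm("basinsdm_single_class",
                  "threshold optimisation needs both classes")
  }
  cand <- if (is.null(grid)) {
    sort(unique(c(0, poo, 1)))
  } else {
    seq(0, 1, by = grid)
  }
  scores <- vapply(cand, function(t) {
    pred <- poo >= t
    sum(pred & y == 1) / P + sum(!pred & y == 0) / N - 1
  }, numeric(1))
  best <- which.max(scores) # which.max returns the first (smallest) optimum
  t <- cand[best]
  pred <- poo >= t
  list(threshold = t, tss = scores[best],
       counts = c(tp = sum(pred & y == 1), fn = sum(!pred & y == 1),
                  tn = sum(!pred & y == 0), fp = sum(pred & y == 0)))
}

#' Ensemble skill on the geographically independent test subset
#'
#' Predicts probabilities of occurrence for the held-out test records (those
#' in macro-basins wholly excluded from training) and reports the maximal
#' TSS over thresholds on the test set. Set `reuse_threshold = TRUE` to
#' score instead at the threshold fixed on the training data.
#'
#' @param m An `ensemble_sdm`.
#' @param dataset The `species_dataset` the model was trained on.
#' @param predictors A [predictor_table()] at the model's level.
#' @param reuse_threshold Use the training threshold instead of
#'   re-optimising on the test set.
#' @return List with `tss`, `threshold`, and confusion `counts`.
#' @export
independent_test_tss <- function(m, dataset, predictors,
                                 reuse_threshold = FALSE) {
  test <- dataset$data |> filter(.data$role == "test")
  if (length(unique(test$label)) < 2L) {
    stop_basinsdm("basinsdm_single_class",
                  "test subset has only one class; TSS undefined")
  }
  poo <- predict_ensemble(m, predictors, test$basin_id)$poo
  if (reuse_threshold) {
    pred <- poo >= m$threshold
    counts <- c(tp = sum(pred & test$label == 1),
                fn = sum(!pred & test$label == 1),
                tn = sum(!pred & test$label == 0),
                fp = sum(pred & test$label == 0))
    list(threshold = m$threshold,
         tss = tss(counts["tp"], counts["fn"], counts["tn"], counts["fp"]),
         counts = counts)
  } else {
    max_tss_threshold(test$label, poo)
  }
}

#' Permutation importance of predictor variables
#'
#' For each variable in turn, its column is permuted `n_perm` times; after
#' each permutation the ensemble predicts again and the Pearson correlation
#' with the unpermuted predictions is recorded. Importance is `1 - mean(r)`:
#' 0 for a variable the model ignores, approaching (and possibly exceeding)
#' 1 for a variable whose shuffling destroys or inverts the predictions.
#' When either prediction vector is constant the correlation is undefined
#' and that permutation contributes `r = 1` (no detectable influence).
#' Variables outside the model's retained set score exactly 0.
#'
#' @param m An `ensemble_sdm`.
#' @param X Data frame of feature rows (conventionally the training
#'   features).
#' @param variables Variables to score (default: the model's retained set).
#' @param n_perm Number of permutations per variable.
#' @param seed Integer seed.
#' @return Tibble `(species_id, level, variable, importance, n_perm)`.
#' @export
permutation_importance <- function(m, X, variables = m$retained_vars,
                                   n_perm = 10, seed = 1) {
  X <- as.data.frame(X)
  base <- predict_ensemble_X(m, X)
  rows <- with_seed(seed, purrr::map(variables, function(v) {
    if (!v %in% m$retained_vars) {
      return(tibble(variable = v, importance = 0, n_perm = as.integer(n_perm)))
    }
    r <- vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[[v]] <- sample(Xp[[v]])
      p <- predict_ensemble_X(m, Xp)
      if (sd(p) == 0 || sd(base) == 0) 1 else cor(base, p)
    }, numeric(1))
    tibble(variable = v, importance = 1 - mean(r),
           n_perm = as.integer(n_perm))
  }))
  bind_rows(rows) |>
    mutate(species_id = m$species_id, level = m$level, .before = 1)
}

#' Compare TSS distributions across resolution levels
#'
#' Levene's test (median-centred) for homogeneity of variance across levels,
#' followed by a one-way repeated-measures ANOVA with species as the
#' repeated unit, testing whether mean skill differs among resolutions.
#'
#' @param tss_table Data frame with columns `species_id`, `level`, `tss`
#'   (one row per species x level, complete cases).
#' @return Tibble `(levene_p, anova_p, n_species, n_levels)`.
#' @export
compare_resolutions <- function(tss_table) {
  d <- as_tibble(tss_table) |>
    mutate(level = factor(.data$level), species_id = factor(.data$species_id))
  counts <- d |> dplyr::count(.data$species_id)
  if (dplyr::n_distinct(counts$n) != 1L) {
    stop_basinsdm("basinsdm_bad_table",
                  "every species needs a TSS at every level")
  }
  lev <- car::leveneTest(tss ~ level, data = d, center = median)
  levene_p <- lev[["Pr(>F)"]][1]
  fit <- aov(tss ~ level + Error(species_id), data = d)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  anova_p <- within[["Pr(>F)"]][1]
  # identical columns give a 0/0 F ratio (up to rounding noise); report the
  # boundary p of 1 when the level effect is numerically zero
  total_ss <- sum((d$tss - mean(d$tss))^2)
  if (within[["Sum Sq"]][1] <= 1e-10 * max(total_ss, 1e-12)) {
    anova_p <- 1
  } else if (is.na(anova_p)) {
    anova_p <- 0
  }
  tibble(levene_p = levene_p, anova_p = anova_p,
         n_species = dplyr::n_distinct(d$species_id),
         n_levels = dplyr::n_distinct(d$level))
}
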