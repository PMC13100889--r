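#' Feature rows for a set of basins
#'
#' @param predictors A [predictor_table()].
#' @param basins Basin ids at the table's level.
#' @param vars Variables to extract (default: all).
#' @return Data frame of features in the order of `basins`.
#' @export
feature_matrix <- function(predictors, basins, vars = predictor_vars(predictors)) {
  miss_v <- setdiff(vars, predictor_vars(predictors))
  if (length(miss_v)) {
    stop_basinsdm("basinsdm_missing_predictor",
                  paste0("variables not in table: ", paste(miss_v, collapse = ", ")))
  }
  idx <- match(basins, predictors$values$basin_id)
  if (anyNA(idx)) {
    stop_basinsdm("basinsdm_unknown_unit",
                  sprintf("basin '%s' has no predictor row",
                          basins[which(is.na(idx))[1]]))
  }
  as.data.frame(predictors$values[idx, vars, drop = FALSE])
}

#' Cross-validated skill of one ensemble member
#'
#' For each of the dataset's `k` folds, fits the learner on the other folds'
#' training records and scores the held-out fold with the maximum TSS over
#' candidate thresholds; returns the mean over folds.
#'
#' @param spec A [learner_spec()].
#' @param dataset A `species_dataset` with assigned folds.
#' @param predictors A [predictor_table()] at the dataset's level.
#' @param vars Feature variables to use.
#' @return Mean cross-validated TSS (a single number).
#' @export
cross_validate <- function(spec, dataset, predictors, vars) {
  train <- dataset$data |> filter(.data$role == "train")
  X <- feature_matrix(predictors, train$basin_id, vars)
  scores <- vapply(seq_len(dataset$k), function(f) {
    hold <- train$fold == f
    fit <- fit_learner(spec, X[!hold, , drop = FALSE], train$label[!hold],
                       train$weight[!hold])
    poo <- predict_prob(fit, X[hold, , drop = FALSE])
    max_tss_threshold(train$label[hold], poo)$tss
  }, numeric(1))
  mean(scores)
}

#' Combine fitted members into a TSS-weighted ensemble
#'
#' Weights are proportional to each member's cross-validated TSS clamped at
#' zero (a below-random member should not pull the ensemble) and renormalised
#' to sum to one; if every member scores at or below zero the ensemble falls
#' back to equal weights and is flagged uninformative. The ensemble's
#' probability of occurrence is the weighted mean of the member
#' probabilities, and the binarisation threshold is set by maximising TSS on
#' the training predictions.
#'
#' @param members Named list of fitted `sdm_learner` objects.
#' @param member_cv_tss Named numeric vector of mean cross-validated TSS.
#' @param X_train Data frame of training features.
#' @param y_train Binary training labels.
#' @param species_id,level Identification carried on the model.
#' @return An `ensemble_sdm` object.
#' @export
build_ensemble <- function(members, member_cv_tss, X_train, y_train,
                           species_id = NA_character_, level = NA_integer_) {
  stopifnot(length(members) == length(member_cv_tss))
  member_cv_tss <- member_cv_tss[names(members)]
  pos <- pmax(member_cv_tss, 0)
  uninformative <- all(pos == 0)
  w <- if (uninformative) rep(1 / length(members), length(members))
       else pos / sum(pos)
  m <- structure(list(
    species_id = species_id, level = as.integer(level),
    members = members, member_cv_tss = member_cv_tss,
    weights = setNames(w, names(members)),
    retained_vars = members[[1]]$features,
    threshold = NA_real_, training_tss = NA_real_,
    uninformative = uninformative), class = "ensemble_sdm")
  poo <- predict_ensemble_X(m, X_train)
  opt <- max_tss_threshold(y_train, poo)
  m$threshold <- opt$threshold
  m$training_tss <- opt$tss
  m
}

# weighted-mean combination over a prepared feature table
predict_ensemble_X <- function(m, X) {
  p <- vapply(m$members, function(mem) predict_prob(mem, X),
              numeric(nrow(X)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  as.numeric(p %*% m$weights)
}

#' Predict ensemble probability of occurrence for basins
#'
#' Applies the trained weighted-mean combination to each basin's feature
#' row. The result is a convex combination of the member probabilities, so
#' it always lies within the member range.
#'
#' @param m An `ensemble_sdm`.
#' @param predictors A [predictor_table()] at the model's level.
#' @param basins Basin ids to predict; defaults to every basin in the table.
#' @return Tibble `(basin_id, poo)`.
#' @export
predict_ensemble <- function(m, predictors, basins = predictors$values$basin_id) {
  X <- feature_matrix(predictors, basins, m$retained_vars)
  tibble(basin_id = basins, poo = predict_ensemble_X(m, X))
}

#' Fit the full ensemble for one species at one level
#'
#' The complete member workflow: each registry member is scored by k-fold
#' cross-validation on the training records, refitted on all training data,
#' and combined by [build_ensemble()] with TSS-proportional weights and a
#' max-TSS training threshold.
#'
#' @param dataset A `species_dataset` from [build_species_dataset()].
#' @param predictors A [predictor_table()] at the dataset's level.
#' @param vars Feature variables (e.g. the collinearity-screened set).
#' @param registry Learner registry (default all nine members).
#' @param seed Integer seed; member seeds derive from it deterministically.
#' @return An `ensemble_sdm` with cross-validated member weights.
#' @export
fit_ensemble <- function(dataset, predictors, vars,
                         registry = learner_registry(), seed = 1) {
  train <- dataset$data |> filter(.data$role == "train")
  X <- feature_matrix(predictors, train$basin_id, vars)
  cv <- numeric(0)
  members <- list()
  for (nm in names(registry)) {
    spec <- registry[[nm]]
    spec$seed <- derive_seed(seed, "member", nm, dataset$species_id,
                             dataset$level)
    cv[nm] <- cross_validate(spec, dataset, predictors, vars)
    members[[nm]] <- fit_learner(spec, X, train$label, train$weight)
  }
  build_ensemble(members, cv, X, train$label,
                 species_id = dataset$species_id, level = dataset$level)
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat("<ensemble_sdm> ", x$species_id, " at level ", x$level, "\n", sep = "")
  cat("  members: ", paste(names(x$members), collapse = ", "), "\n", sep = "")
  cat(sprintf("  threshold = %.3f, training TSS = %.3f%s\n", x$threshold,
              x$training_tss,
              if (x$uninformative) " (uninformative: equal weights)" else ""))
  invisible(x)
}

#' Tidy an ensemble: one row per member
#'
#' @param x An `ensemble_sdm`.
#' @param ... Unused.
#' @return Tibble `(species_id, level, member, cv_tss, weight)`.
#' @export
tidy.ensemble_sdm <- function(x, ...) {
  tibble(species_id = x$species_id, level = x$level,
         member = names(x$members),
         cv_tss = unname(x$member_cv_tss),
         weight = unname(x$weights))
}

#' One-row summary of an ensemble
#'
#' @param x An `ensemble_sdm`.
#' @param ... Unused.
#' @return Tibble with the threshold, training TSS, member count and the
#'   uninformative flag.
#' @export
glance.ensemble_sdm <- function(x, ...) {
  tibble(species_id = x$species_id, level = x$level,
         n_members = length(x$members), threshold = x$threshold,
         training_tss = x$training_tss, uninformative = x$uninformative)
}

#' Serialise an ensemble's manifest as JSON
#'
#' Writes the reproducibility summary of a fitted ensemble: member names,
#' cross-validated TSS, weights, threshold, retained variables and the
#' uninformative flag. Fitted member objects themselves are not serialised;
#' refitting from the run manifest's seeds reproduces them exactly.
#'
#' @param m An `ensemble_sdm`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_manifest <- function(m, path) {
  jsonlite::write_json(list(
    species_id = m$species_id, level = m$level,
    members = names(m$members),
    member_cv_tss = as.list(m$member_cv_tss),
    weights = as.list(m$weights),
    threshold = m$threshold, training_tss = m$training_tss,
    retained_vars = m$retained_vars,
    uninformative = m$uninformative
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
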