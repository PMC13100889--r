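#' The nine-member learner registry
#'
#' The ensemble combines two classification methods (CTA: classification
#' tree; FDA: discriminant analysis on a flexible spline basis), three
#' regression techniques (GLM: logistic regression; GAM: additive logistic
#' regression; MARS: adaptive-spline logistic regression), and four
#' machine-learning techniques (ANN: single-hidden-layer neural network;
#' BRT: gradient-boosted trees; RF: random forest; MAXENT: ridge-penalised
#' logistic regression on linear plus quadratic features fitted to presences
#' against target-group background). Every member honours per-record weights
#' (for the discriminant member, weights enter through the weighted class
#' priors, which is exact when weights are constant within class, as they
#' are throughout this package) and exposes the same probabilistic
#' prediction contract.
#'
#' @param names Optional subset of member names to return.
#' @return Named list of learner specifications (`learner_spec` objects).
#' @export
#' @examples
#' names(learner_registry())
learner_registry <- function(names = NULL) {
  reg <- list(
    CTA = learner_spec("CTA", list(cp = 0.005, minbucket = 5)),
    FDA = learner_spec("FDA", list(df = 3)),
    GLM = learner_spec("GLM", list()),
    GAM = learner_spec("GAM", list(k = 5)),
    MARS = learner_spec("MARS", list(df = 4)),
    ANN = learner_spec("ANN", list(size = 5, decay = 0.01, maxit = 200)),
    BRT = learner_spec("BRT", list(nrounds = 100, max_depth = 3, eta = 0.1)),
    RF = learner_spec("RF", list(num_trees = 150)),
    MAXENT = learner_spec("MAXENT", list(lambda = 0.01))
  )
  if (is.null(names)) return(reg)
  unknown <- setdiff(names, names(reg))
  if (length(unknown)) {
    stop_basinsdm("basinsdm_unknown_learner",
                  paste0("unknown learners: ", paste(unknown, collapse = ", ")))
  }
  reg[names]
}

#' @rdname learner_registry
#' @param name Member name (one of the registry's nine).
#' @param params Named list of hyperparameters overriding the defaults.
#' @param seed Integer seed used by stochastic members.
#' @export
learner_spec <- function(name, params = list(), seed = 1L) {
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Fit one ensemble member
#'
#' Fits the learner named by `spec` to a feature table and binary labels and
#' wraps it behind the common contract: the returned `sdm_learner` predicts
#' probabilities in `[0, 1]` via [predict_prob()] and is deterministic given
#' `spec$seed`.
#'
#' @param spec A [learner_spec()].
#' @param X Data frame of numeric features (no missing values).
#' @param y Binary labels (0/1).
#' @param w Nonnegative per-record weights (default all 1).
#' @return An `sdm_learner` object.
#' @export
fit_learner <- function(spec, X, y, w = rep(1, length(y))) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop_basinsdm("basinsdm_single_class",
                  "need at least 2 records of each class to fit")
  }
  if (!all(vapply(X, is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(X)))) {
    stop_basinsdm("basinsdm_bad_features",
                  "features must be numeric and finite")
  }
  if (length(w) != length(y) || any(!is.finite(w) | w < 0)) {
    stop_basinsdm("basinsdm_bad_weights", "weights must be nonnegative")
  }
  fitter <- switch(spec$name,
    CTA = fit_cta, FDA = fit_fda, GLM = fit_glm, GAM = fit_gam,
    MARS = fit_mars, ANN = fit_ann, BRT = fit_brt, RF = fit_rf,
    MAXENT = fit_maxent,
    stop_basinsdm("basinsdm_unknown_learner",
                  sprintf("unknown learner '%s'", spec$name)))
  fit <- with_seed(spec$seed, fitter(X, y, w, spec$params, spec$seed))
  structure(list(spec = spec, fit = fit, features = names(X)),
            class = "sdm_learner")
}

#' @rdname fit_learner
#' @param object An `sdm_learner`.
#' @param newdata Data frame containing the training feature columns.
#' @return `predict_prob()` returns a numeric vector of occurrence
#'   probabilities, one per row of `newdata`.
#' @export
predict_prob <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop_basinsdm("basinsdm_missing_predictor",
                  paste0("newdata lacks features: ", paste(miss, collapse = ", ")))
  }
  p <- object$fit$predict(newdata[object$features])
  pmin(1, pmax(0, as.numeric(p)))
}

#' @export
print.sdm_learner <- function(x, ...) {
  cat("<sdm_learner> ", x$spec$name, " on ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

# --- member implementations -------------------------------------------------
# each returns list(predict = function(newdata) probabilities)

quote_names <- function(v) paste0("`", v, "`")

fit_cta <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = factor(y, levels = c(0, 1)))
  fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                      control = rpart::rpart.control(
                        cp = p$cp %||% 0.005, minbucket = p$minbucket %||% 5))
  list(predict = function(nd) predict(fit, nd, type = "prob")[, "1"])
}

spline_formula <- function(X, df, response = ".y") {
  terms <- vapply(names(X), function(v) {
    x <- X[[v]]
    # quantile knots must be strictly interior and distinct, otherwise the
    # basis is singular (zero-inflated variables like dam density)
    kn <- quantile(x, probs = seq(0, 1, length.out = df + 1))
    interior <- kn[-c(1, df + 1)]
    ok <- length(unique(x)) > df + 1 &&
      all(interior > min(x)) && all(interior < max(x)) &&
      !anyDuplicated(interior)
    if (ok) {
      sprintf("splines::ns(%s, df = %d)", quote_names(v), df)
    } else {
      quote_names(v)
    }
  }, character(1))
  as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

fit_fda <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = factor(y, levels = c(0, 1)))
  pri <- c(sum(w[y == 0]), sum(w[y == 1]))
  f <- spline_formula(X, p$df %||% 3)
  environment(f) <- environment()
  fit <- MASS::lda(f, data = d, prior = pri / sum(pri))
  list(predict = function(nd) predict(fit, nd)$posterior[, "1"])
}

fit_glm <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = y)
  fit <- suppressWarnings(glm(.y ~ ., data = d, family = binomial(),
                              weights = w))
  list(predict = function(nd)
    suppressWarnings(predict(fit, nd, type = "response")))
}

fit_gam <- function(X, y, w, p, seed) {
  k <- p$k %||% 5
  terms <- vapply(names(X), function(v) {
    if (length(unique(X[[v]])) > 2 * k) {
      sprintf("s(%s, k = %d)", quote_names(v), k)
    } else {
      quote_names(v)
    }
  }, character(1))
  d <- cbind(X, .y = y)
  f <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  # the discretised fitter scales to the larger basin tables; plain gam is
  # more robust at small n
  if (nrow(X) >= 500) {
    fit <- suppressWarnings(mgcv::bam(f, data = d, family = binomial(),
                                      weights = w, discrete = TRUE))
  } else {
    fit <- suppressWarnings(mgcv::gam(f, data = d, family = binomial(),
                                      weights = w, method = "REML"))
  }
  list(predict = function(nd)
    as.numeric(predict(fit, nd, type = "response")))
}

fit_mars <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = y)
  f <- spline_formula(X, p$df %||% 4)
  environment(f) <- environment()
  fit <- suppressWarnings(glm(f, data = d, family = binomial(), weights = w))
  list(predict = function(nd)
    suppressWarnings(predict(fit, nd, type = "response")))
}

fit_ann <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = factor(y, levels = c(0, 1)))
  # features are standardised so the weight-decay penalty is scale-free
  ctr <- lapply(X, function(x) c(m = mean(x), s = max(sd(x), 1e-12)))
  Xs <- as.data.frame(imap(X, ~ (.x - ctr[[.y]]["m"]) / ctr[[.y]]["s"]))
  ds <- cbind(Xs, .y = d$.y)
  fit <- nnet::nnet(.y ~ ., data = ds, weights = w,
                    size = p$size %||% 5, decay = p$decay %||% 0.01,
                    maxit = p$maxit %||% 200, trace = FALSE)
  list(predict = function(nd) {
    nds <- as.data.frame(imap(nd, ~ (.x - ctr[[.y]]["m"]) / ctr[[.y]]["s"]))
    as.numeric(predict(fit, nds, type = "raw"))
  })
}

fit_brt <- function(X, y, w, p, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = p$max_depth %||% 3, eta = p$eta %||% 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = p$nrounds %||% 100, verbose = 0)
  feats <- names(X)
  list(predict = function(nd) predict(fit, as.matrix(nd[feats])))
}

fit_rf <- function(X, y, w, p, seed) {
  d <- cbind(X, .y = factor(y, levels = c(0, 1)))
  fit <- ranger::ranger(.y ~ ., data = d, probability = TRUE,
                        num.trees = p$num_trees %||% 150, case.weights = w,
                        seed = seed, num.threads = 1)
  list(predict = function(nd)
    predict(fit, nd, num.threads = 1)$predictions[, "1"])
}

fit_maxent <- function(X, y, w, p, seed) {
  # linear + quadratic feature expansion, ridge penalty: the regularised
  # exponential-family model underlying maximum-entropy SDMs, fitted as
  # weighted logistic regression of presences against background
  expand <- function(Z) {
    M <- as.matrix(Z)
    cbind(M, M^2)
  }
  fit <- suppressWarnings(
    glmnet::glmnet(expand(X), y, family = "binomial", alpha = 0,
                   weights = w, lambda = c(1, 0.1, p$lambda %||% 0.01),
                   standardize = TRUE))
  lam <- p$lambda %||% 0.01
  list(predict = function(nd)
    as.numeric(predict(fit, expand(nd), s = lam, type = "response")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configure the learner registry from YAML
#'
#' The file maps member names to hyperparameters and optional seeds:
#' ```yaml
#' members:
#'   - name: RF
#'     params: {num_trees: 500}
#'     seed: 3
#'   - name: GLM
#' ```
#'
#' @param path YAML file path.
#' @return Named list of [learner_spec()] objects.
#' @export
read_learner_registry <- function(path) {
  conf <- yaml::read_yaml(path)
  base <- learner_registry()
  specs <- lapply(conf$members, function(m) {
    if (!m$name %in% names(base)) {
      stop_basinsdm("basinsdm_unknown_learner",
                    sprintf("unknown learner '%s'", m$name))
    }
    spec <- base[[m$name]]
    spec$params <- utils::modifyList(spec$params, m$params %||% list())
    if (!is.null(m$seed)) spec$seed <- as.integer(m$seed)
    spec
  })
  setNames(specs, vapply(conf$members, `[[`, character(1), "name"))
}
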