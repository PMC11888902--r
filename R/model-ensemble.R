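#' Class-probability predictions
#'
#' Uniform inference interface for every classifier in the package. Rows
#' sum to 1; column `"1"` is the hypertensive (positive) class.
#'
#' @param model a fitted model.
#' @param X numeric feature matrix.
#' @param ... passed to methods.
#' @return A numeric matrix `[n x 2]` with columns `"0"`, `"1"`.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' Ensemble configuration
#'
#' The base-learner pool used by the stacking and soft-voting ensembles:
#' a random forest, a classic gradient-boosting machine (shallow trees,
#' shrinkage 0.1) and an extreme-gradient-boosting learner. Stacking adds a
#' logistic-regression meta-learner fitted on out-of-fold base-learner
#' probabilities.
#'
#' @param base_learners character subset of `c("rf", "gbm", "xgb")`
#'   (at least two).
#' @param n_trees trees per tree-based learner.
#' @param cross_fit_folds folds for stacking's out-of-fold meta-features.
#' @param seed integer seed.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(base_learners = c("rf", "gbm", "xgb"),
                            n_trees = 100L, cross_fit_folds = 5L,
                            seed = 1L) {
  base_learners <- match.arg(base_learners, several.ok = TRUE)
  if (length(base_learners) < 2L) stop_bcg("need at least 2 base learners")
  structure(list(base_learners = base_learners, n_trees = as.integer(n_trees),
                 cross_fit_folds = as.integer(cross_fit_folds),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# --- base learners, each returning an object with a predict_proba method ---

fit_base <- function(kind, X, y, cfg) {
  X <- as.matrix(X)
  y <- label_to_int(y)
  switch(kind,
    rf = {
      fit <- with_seed(derive_seed(cfg$seed, 11L),
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = cfg$n_trees))
      structure(list(fit = fit), class = c("bcg_rf", "bcg_model"))
    },
    gbm = {
      # classic GBM parameterisation: shallow trees, shrinkage 0.1,
      # no column subsampling, no L2 penalty
      fit <- with_seed(derive_seed(cfg$seed, 12L), xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, subsample = 1, colsample_bytree = 1,
                      lambda = 0, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = cfg$n_trees, verbose = 0))
      structure(list(fit = fit), class = c("bcg_xgb", "bcg_model"))
    },
    xgb = {
      fit <- with_seed(derive_seed(cfg$seed, 13L), xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.3,
                      max_depth = 6, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = cfg$n_trees, verbose = 0))
      structure(list(fit = fit), class = c("bcg_xgb", "bcg_model"))
    },
    stop_bcg(sprintf("unknown base learner '%s'", kind))
  )
}

#' @export
predict_proba.bcg_rf <- function(model, X, ...) {
  p <- stats::predict(model$fit, as.matrix(X), type = "prob")
  p <- unname(p)
  colnames(p) <- c("0", "1")
  p
}

#' @export
predict_proba.bcg_xgb <- function(model, X, ...) {
  p1 <- stats::predict(model$fit, as.matrix(X))
  cbind("0" = 1 - p1, "1" = p1)
}

#' Standalone extreme-gradient-boosting classifier
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels (hypertensive = 1).
#' @param cfg an [ensemble_config()] (supplies `n_trees` and `seed`).
#' @return A fitted model with a [predict_proba()] method.
#' @export
fit_xgb <- function(X, y, cfg = ensemble_config()) {
  check_two_classes(label_to_int(y))
  fit_base("xgb", X, y, cfg)
}

# stratified fold assignment of 1..n given labels; plain (non-group) version
# used for stacking's internal cross-fitting
stratified_fold_ids <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stacking ensemble
#'
#' Base learners are fitted on the full training set for inference; the
#' logistic-regression meta-learner is fitted on out-of-fold base-learner
#' probability predictions (k-fold cross-fitting) so it never sees
#' probabilities produced by a model that was trained on the same rows.
#'
#' @inheritParams fit_xgb
#' @return An object of class `bcg_stacking` with the fitted base learners,
#'   the meta-model, and the `meta_features` matrix
#'   (`n x (n_bases * n_classes)`).
#' @export
fit_stacking <- function(X, y, cfg = ensemble_config()) {
  X <- as.matrix(X)
  y <- label_to_int(y)
  check_two_classes(y)
  n <- nrow(X)
  k <- cfg$cross_fit_folds
  meta <- matrix(NA_real_, n, 2L * length(cfg$base_learners))
  colnames(meta) <- as.vector(outer(c("p0", "p1"), cfg$base_learners,
                                    function(p, b) paste(b, p, sep = "_")))
  folds <- with_seed(derive_seed(cfg$seed, 21L), stratified_fold_ids(y, k))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L)
      stop_bcg("a cross-fit fold lost one class; use fewer folds")
    for (b in seq_along(cfg$base_learners)) {
      m <- fit_base(cfg$base_learners[b], X[tr, , drop = FALSE], y[tr], cfg)
      meta[!tr, (2L * b - 1L):(2L * b)] <-
        predict_proba(m, X[!tr, , drop = FALSE])
    }
  }
  bases <- lapply(cfg$base_learners, function(b) fit_base(b, X, y, cfg))
  names(bases) <- cfg$base_learners
  meta_df <- as.data.frame(meta)
  meta_df$.y <- y
  meta_fit <- suppressWarnings(
    stats::glm(.y ~ ., data = meta_df, family = stats::binomial()))
  structure(list(bases = bases, meta = meta_fit, meta_features = meta,
                 cfg = cfg),
            class = c("bcg_stacking", "bcg_model"))
}

#' @export
predict_proba.bcg_stacking <- function(model, X, ...) {
  X <- as.matrix(X)
  meta <- do.call(cbind, lapply(model$bases, function(b) predict_proba(b, X)))
  colnames(meta) <- colnames(model$meta_features)
  p1 <- unname(suppressWarnings(
    stats::predict(model$meta, newdata = as.data.frame(meta),
                   type = "response")))
  cbind("0" = 1 - p1, "1" = p1)
}

#' Soft-voting ensemble
#'
#' Each base learner is fitted independently; the ensemble probability is
#' the uniform average of the base probabilities, and the predicted label
#' is the argmax with ties broken toward the lower class index.
#'
#' @inheritParams fit_xgb
#' @return An object of class `bcg_voting`.
#' @export
fit_voting <- function(X, y, cfg = ensemble_config()) {
  X <- as.matrix(X)
  y <- label_to_int(y)
  check_two_classes(y)
  bases <- lapply(cfg$base_learners, function(b) fit_base(b, X, y, cfg))
  names(bases) <- cfg$base_learners
  structure(list(bases = bases, cfg = cfg),
            class = c("bcg_voting", "bcg_model"))
}

#' @export
predict_proba.bcg_voting <- function(model, X, ...) {
  ps <- lapply(model$bases, function(b) predict_proba(b, X))
  Reduce(`+`, ps) / length(ps)
}

#' Predicted class labels
#'
#' Argmax of [predict_proba()], ties broken toward class 0.
#'
#' @inheritParams predict_proba
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, X, ...) {
  p <- predict_proba(model, X, ...)
  as.integer(p[, "1"] > p[, "0"])
}
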