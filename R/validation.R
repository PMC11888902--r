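# group label = label of the first member (groups are recordings, whose
# segments all share the recording's label)
group_table <- function(labels, groups) {
  first <- !duplicated(groups)
  data.frame(group = groups[first], label = labels[first],
             stringsAsFactors = FALSE)
}

#' Hold-out train/test split
#'
#' Stratified by label; when `group_aware` (the default) all segments of
#' one source recording land on the same side of the split, preventing
#' twin-segment leakage. Deterministic given `seed`.
#'
#' @param labels 0/1 label vector, one entry per sample (segment).
#' @param groups group (recording) identifier per sample; ignored when
#'   `group_aware = FALSE` or `NULL` (each sample is its own group).
#' @param test_fraction fraction held out for testing, in (0, 1).
#' @param stratified preserve class proportions across the split.
#' @param group_aware keep whole groups on one side.
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(labels, groups = NULL, test_fraction = 0.25,
                          stratified = TRUE, group_aware = TRUE, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_bcg("test_fraction must lie in (0, 1)")
  labels <- label_to_int(labels)
  n <- length(labels)
  if (is.null(groups) || !group_aware) groups <- seq_len(n)
  gt <- group_table(labels, groups)
  test_groups <- with_seed(seed, {
    if (stratified) {
      # per-class quotas by largest remainder, so the overall test size is
      # round(n_groups * test_fraction)
      classes <- unique(gt$label)
      sizes <- vapply(classes, function(cl) sum(gt$label == cl), integer(1))
      quota <- sizes * test_fraction
      n_test <- pmax(1L, floor(quota))
      left <- max(0L, round(nrow(gt) * test_fraction) - sum(n_test))
      if (left > 0) {
        extra <- order(quota - floor(quota), decreasing = TRUE)
        n_test[extra[seq_len(min(left, length(extra)))]] <-
          n_test[extra[seq_len(min(left, length(extra)))]] + 1L
      }
      if (any(n_test >= sizes))
        stop_bcg("test_fraction leaves no training groups for a class")
      unlist(lapply(seq_along(classes), function(i)
        sample(gt$group[gt$label == classes[i]], n_test[i])))
    } else {
      n_test <- max(1L, round(nrow(gt) * test_fraction))
      sample(gt$group, n_test)
    }
  })
  test <- which(groups %in% test_groups)
  train <- setdiff(seq_len(n), test)
  for (side in list(train, test))
    if (length(unique(labels[side])) < 2L)
      stop_bcg("a class is absent from one side of the split")
  list(train = train, test = test)
}

#' Stratified (group-aware) k-fold partitions
#'
#' Folds are disjoint with union equal to the full index set; class
#' proportions are preserved per fold, and with `group_aware` every group
#' (recording) appears in exactly one test fold.
#'
#' @inheritParams holdout_split
#' @param k number of folds (>= 2).
#' @return A list of `k` elements, each a list with `train` and `test`
#'   index vectors.
#' @export
kfold_cv <- function(labels, groups = NULL, k = 5L, stratified = TRUE,
                     group_aware = TRUE, seed = 1L) {
  if (k < 2L) stop_bcg("k must be >= 2")
  labels <- label_to_int(labels)
  n <- length(labels)
  if (is.null(groups) || !group_aware) groups <- seq_len(n)
  gt <- group_table(labels, groups)
  if (k > nrow(gt)) stop_bcg("k exceeds the number of groups")
  fold_of_group <- with_seed(seed, {
    fold <- integer(nrow(gt))
    if (stratified) {
      for (cl in unique(gt$label)) {
        idx <- sample(which(gt$label == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(nrow(gt))] <- rep_len(seq_len(k), nrow(gt))
    }
    fold
  })
  names(fold_of_group) <- as.character(gt$group)
  fold_idx <- unname(fold_of_group[as.character(groups)])
  lapply(seq_len(k), function(f)
    list(train = which(fold_idx != f), test = which(fold_idx == f)))
}

# trainer registry: model name -> function(X, y) -> fitted model
get_trainer <- function(model, seed) {
  if (is.list(model) && is.function(model$fit)) return(model$fit)
  if (!is.character(model))
    stop_bcg("model must be a name or a list with a $fit function")
  switch(model,
    fclstm = function(X, y)
      train_fclstm(X, y, train_config("fclstm", seed = seed)),
    transformer = function(X, y)
      train_transformer(X, y, train_config("transformer", seed = seed)),
    stacking = function(X, y) fit_stacking(X, y, ensemble_config(seed = seed)),
    voting = function(X, y) fit_voting(X, y, ensemble_config(seed = seed)),
    xgb = function(X, y) fit_xgb(X, y, ensemble_config(seed = seed)),
    stop_bcg(sprintf("unknown model '%s'", model))
  )
}

parse_scheme <- function(scheme) {
  parts <- strsplit(scheme, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("holdout", "cv"))
    stop_bcg("scheme must be 'holdout:<fraction>' or 'cv:<k>'")
  list(kind = parts[1], value = as.numeric(parts[2]))
}

split_report <- function(y_test, pred, p1, split_desc, seed) {
  cm <- confusion(y_test, pred)
  bm <- basic_metrics(cm)
  roc <- roc_auc(y_test, p1)
  structure(list(
    accuracy = unname(bm["accuracy"]), f1 = unname(bm["f1"]),
    precision = unname(bm["precision"]), jaccard = unname(bm["jaccard"]),
    kappa = cohens_kappa(y_test, pred),
    sensitivity = unname(bm["sensitivity"]),
    specificity = unname(bm["specificity"]),
    auc = roc$auc, mcnemar_p = NA_real_,
    roc_points = roc$roc_points, confusion = cm,
    split = split_desc, seed = seed,
    y_true = y_test, y_pred = pred, scores = p1
  ), class = "bcg_split_report")
}

METRIC_FIELDS <- c("accuracy", "f1", "precision", "jaccard", "kappa",
                   "sensitivity", "specificity", "auc")

#' Train and evaluate a classifier under a validation scheme
#'
#' Supports hold-out validation (`"holdout:0.5"`, `"holdout:0.25"`) and
#' stratified k-fold cross-validation (`"cv:5"`, `"cv:10"`), group-aware by
#' default. For every split the features are standardised with
#' train-fitted parameters, the model is trained on the train side and all
#' metrics are computed on the test side. Cross-validation reports per-fold
#' metrics and their unweighted mean.
#'
#' @param model a model name (`"fclstm"`, `"transformer"`, `"stacking"`,
#'   `"voting"`, `"xgb"`) or a list with a `$fit(X, y)` function returning
#'   an object with a [predict_proba()] method.
#' @param features numeric feature matrix or a [build_feature_table()] data
#'   frame (label/grouping columns are then taken from it unless given).
#' @param labels 0/1 labels; defaults to the table's `label` column.
#' @param groups recording ids; defaults to the table's `source_id` column.
#' @param scheme validation scheme descriptor.
#' @param seed integer seed controlling the split and the model.
#' @param group_aware keep segments of one recording on one side of every
#'   split.
#' @return An object of class `bcg_eval_report`: for hold-out a single
#'   split report; for CV a list with `folds` (split reports) and `mean`
#'   (unweighted mean of each metric).
#' @export
evaluate_model <- function(model, features, labels = NULL, groups = NULL,
                           scheme = "holdout:0.25", seed = 1L,
                           group_aware = TRUE) {
  if (is.data.frame(features)) {
    labels <- labels %||% features$label
    groups <- groups %||% features$source_id
    features <- feature_matrix(features)
  }
  if (is.null(labels)) stop_bcg("labels are required")
  labels <- label_to_int(labels)
  trainer <- get_trainer(model, seed = derive_seed(seed, 101L))
  sch <- parse_scheme(scheme)
  run_split <- function(idx, desc) {
    std <- standardize_features(features[idx$train, , drop = FALSE],
                                test = features[idx$test, , drop = FALSE])
    fit <- trainer(std$train, labels[idx$train])
    p <- predict_proba(fit, std$test)
    pred <- as.integer(p[, "1"] > p[, "0"])
    split_report(labels[idx$test], pred, p[, "1"], desc, seed)
  }
  if (sch$kind == "holdout") {
    idx <- holdout_split(labels, groups, test_fraction = sch$value,
                         group_aware = group_aware, seed = seed)
    rep <- run_split(idx, sprintf("holdout:%g", sch$value))
    class(rep) <- c("bcg_eval_report", class(rep))
    return(rep)
  }
  k <- as.integer(sch$value)
  folds <- kfold_cv(labels, groups, k = k, group_aware = group_aware,
                    seed = seed)
  reports <- lapply(seq_len(k), function(f)
    run_split(folds[[f]], sprintf("cv:%d fold %d", k, f)))
  mean_metrics <- vapply(METRIC_FIELDS, function(m)
    mean(vapply(reports, function(r) r[[m]], numeric(1))), numeric(1))
  structure(list(folds = reports, mean = mean_metrics,
                 split = sprintf("cv:%d", k), seed = seed),
            class = c("bcg_eval_report", "bcg_cv_report"))
}

#' @export
print.bcg_eval_report <- function(x, ...) {
  if (inherits(x, "bcg_cv_report")) {
    cat(sprintf("<bcg_eval_report> %s (%d folds), mean metrics:\n",
                x$split, length(x$folds)))
    print(round(x$mean, 4))
  } else {
    cat(sprintf("<bcg_eval_report> %s\n", x$split))
    print(round(vapply(METRIC_FIELDS, function(m) x[[m]], numeric(1)), 4))
  }
  invisible(x)
}

#' Pairwise model comparison with McNemar's test
#'
#' @param y_true 0/1 truth on a common test set.
#' @param pred_a,pred_b the two models' predictions on it.
#' @param correction continuity correction (default off).
#' @return See [mcnemar_test()].
#' @export
compare_models <- function(y_true, pred_a, pred_b, correction = FALSE) {
  mcnemar_test(y_true, pred_a, pred_b, correction = correction)
}
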