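# Gradient-boosted-tree classification: grouped random-search tuning,
# fitting, evaluation metrics, nested cross-validation over cluster-grouped
# folds, final-model training, and the shuffled-label control.

#' Gradient-booster configuration
#'
#' Defaults sit inside the tuning search ranges: trees 100-400, learning rate
#' 0.01-0.2 (log-uniform), depth 3-10, column subsample 0.1-0.9.
#'
#' @param n_trees,learning_rate,max_depth,colsample_bytree booster
#'   hyperparameters.
#' @param seed integer seed.
#' @return a `booster_config`.
#' @export
booster_config <- function(n_trees = 200L, learning_rate = 0.1,
                           max_depth = 6L, colsample_bytree = 0.8,
                           seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 colsample_bytree = colsample_bytree, seed = as.integer(seed)),
            class = "booster_config")
}

sample_booster_config <- function(u, seed) {
  booster_config(
    n_trees = 100L + as.integer(floor(u[1] * 301)),
    learning_rate = exp(log(0.01) + u[2] * (log(0.2) - log(0.01))),
    max_depth = 3L + as.integer(floor(u[3] * 8)) %% 8L,
    colsample_bytree = 0.1 + u[4] * 0.8,
    seed = seed)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated summary `sum((R_i - R_{i-1}) * P_i)` over descending
#' score order with tie-aware grouping.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0L) return(0)
  ord <- order(-scores)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' ROC-AUC with tie-aware ranking
#'
#' Equivalent to the trapezoidal area under the ROC curve; computed from the
#' Mann-Whitney statistic with midranks, so tied scores contribute half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes present).
#' @return area under the ROC curve.
#' @export
roc_auc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    stop("ROC-AUC needs both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification evaluation report
#'
#' Thresholds the probabilities at `threshold` and reports the confusion
#' counts together with precision, F1, balanced accuracy, MCC (defined 0 when
#' any marginal is empty) and ROC-AUC.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return an `eval_report`: list of metrics, confusion counts and the stored
#'   probabilities.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  if (length(labels) == 0L) stop("Empty evaluation input", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("Probabilities must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  auc <- if (length(unique(labels)) == 2L) roc_auc(probabilities, labels)
         else NA_real_
  structure(list(roc_auc = auc, mcc = mcc, f1 = f1, precision = precision,
                 balanced_accuracy = (recall + specificity) / 2,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 threshold = threshold, probabilities = probabilities,
                 labels = labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> ROC-AUC %.3f | MCC %.3f | F1 %.3f | ",
                     "BalAcc %.3f | Precision %.3f\n"),
              x$roc_auc, x$mcc, x$f1, x$balanced_accuracy, x$precision))
  cat(sprintf("  confusion (t=%.2f): TP %d FP %d FN %d TN %d\n", x$threshold,
              x$confusion[["tp"]], x$confusion[["fp"]], x$confusion[["fn"]],
              x$confusion[["tn"]]))
  invisible(x)
}

#' Fit the gradient-boosted classifier
#'
#' @param x a `feature_matrix` of selected training features.
#' @param labels binary labels (both classes required).
#' @param config a [booster_config()].
#' @return a `booster_model` wrapping the xgboost handle and the training
#'   column names.
#' @export
fit_booster <- function(x, labels, config = booster_config()) {
  if (length(unique(labels)) < 2L) {
    stop("Cannot fit a classifier on constant labels", call. = FALSE)
  }
  vals <- unclass(x)
  dm <- xgboost::xgb.DMatrix(vals, label = labels)
  bst <- xgboost::xgb.train(params = xgb_params(config), data = dm,
                            nrounds = config$n_trees, verbose = 0)
  structure(list(booster = bst, config = config, features = colnames(vals)),
            class = "booster_model")
}

#' Predicted probabilities from a fitted booster
#'
#' @param model a `booster_model`.
#' @param x a `feature_matrix` with exactly the training columns.
#' @return numeric probabilities.
#' @export
predict_booster <- function(model, x) {
  vals <- unclass(x)
  if (!identical(colnames(vals), model$features)) {
    if (!all(model$features %in% colnames(vals))) {
      stop("Feature columns do not match the fitted model", call. = FALSE)
    }
    vals <- vals[, model$features, drop = FALSE]
  }
  stats::predict(model$booster, vals)
}

#' Random-search booster tuning on grouped inner folds
#'
#' Samples `n_iter` configurations from the search ranges and scores each by
#' mean average precision over `inner_k` stratified grouped folds; single-
#' class folds are skipped with a warning. Returns the argmax configuration.
#'
#' @param x training `feature_matrix` (already masked).
#' @param labels binary labels.
#' @param groups cluster id per training row.
#' @param n_iter number of sampled configurations (default 15).
#' @param inner_k inner folds (default 3).
#' @param seed integer seed.
#' @return list with `config` (best [booster_config()]) and `trials`.
#' @export
tune_booster <- function(x, labels, groups, n_iter = 15L, inner_k = 3L,
                         seed = 1L) {
  rng <- local_rng(seed)
  folds <- stratified_group_kfold(seq_along(labels), labels, groups,
                                  k = inner_k, seed = seed)
  draws <- sample_local(rng, 1e6, size = 4L * n_iter) / 1e6
  trials <- data.frame()
  best <- NULL
  for (k in seq_len(n_iter)) {
    cfg <- sample_booster_config(draws[(k - 1L) * 4L + 1:4], seed)
    scores <- numeric(0)
    for (f in folds) {
      ytr <- labels[f$train]; yval <- labels[f$val]
      if (length(unique(ytr)) < 2L || length(unique(yval)) < 2L) {
        warning("Skipping single-class inner fold during tuning",
                call. = FALSE)
        next
      }
      fit <- fit_booster(fm_rows(x, f$train), ytr, cfg)
      p <- predict_booster(fit, fm_rows(x, f$val))
      scores <- c(scores, average_precision(p, yval))
    }
    sc <- if (length(scores) > 0L) mean(scores) else -Inf
    trials <- rbind(trials, data.frame(
      trial = k, n_trees = cfg$n_trees, learning_rate = cfg$learning_rate,
      max_depth = cfg$max_depth, colsample_bytree = cfg$colsample_bytree,
      mean_ap = sc))
    if (is.null(best) || sc > best$score) best <- list(config = cfg, score = sc)
  }
  list(config = best$config, trials = trials)
}

# Median combination of fold-level booster configurations (categoricals would
# take the mode; all current fields are numeric, ties round down).
median_config <- function(configs, seed = 1L) {
  med <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  }
  booster_config(
    n_trees = as.integer(floor(med(vapply(configs, `[[`, numeric(1), "n_trees")))),
    learning_rate = med(vapply(configs, `[[`, numeric(1), "learning_rate")),
    max_depth = as.integer(floor(med(vapply(configs, `[[`, numeric(1), "max_depth")))),
    colsample_bytree = med(vapply(configs, `[[`, numeric(1), "colsample_bytree")),
    seed = seed)
}
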