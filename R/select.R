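# Per-fold feature selection: target-frequency filter, Pearson correlation
# pruning, and recursive feature elimination (RFE) with a gradient-boosted
# estimator. Every stage consumes training-fold rows only; held-out rows are
# reduced by applying the resulting mask.

#' Drop rarely-annotated target features
#'
#' `TARGET`-family columns annotated for fewer than `min_count` compounds (in
#' the supplied matrix, i.e. the training fold) are removed; other families
#' are untouched.
#'
#' @param x a `feature_matrix`.
#' @param min_count minimum annotation count (default 2).
#' @return filtered `feature_matrix`.
#' @export
filter_target_frequency <- function(x, min_count = 2L) {
  fam <- feature_families(x)
  drop <- fam == "TARGET" & colSums(unclass(x)) < min_count
  if (!any(drop)) return(x)
  fm_select(x, which(!drop))
}

#' Prune highly correlated features
#'
#' Iterates columns in stable input order and drops any column whose absolute
#' Pearson correlation with an already-retained column exceeds `threshold`.
#' Constant columns (undefined correlation) are dropped.
#'
#' @param x a `feature_matrix`.
#' @param threshold absolute-correlation threshold (default 0.8).
#' @return filtered `feature_matrix`.
#' @export
correlation_filter <- function(x, threshold = 0.8) {
  vals <- unclass(x)
  sds <- apply(vals, 2, stats::sd)
  keep_candidates <- which(sds > 0)
  if (length(keep_candidates) == 0L) {
    stop("All columns are constant; nothing to retain", call. = FALSE)
  }
  cm <- abs(suppressWarnings(stats::cor(vals[, keep_candidates, drop = FALSE])))
  retained <- integer(0)
  for (k in seq_along(keep_candidates)) {
    if (length(retained) == 0L ||
        all(cm[k, retained] <= threshold, na.rm = TRUE)) {
      retained <- c(retained, k)
    }
  }
  fm_select(x, keep_candidates[retained])
}

xgb_params <- function(config) {
  list(objective = "binary:logistic", eval_metric = "auc",
       max_depth = config$max_depth, eta = config$learning_rate,
       colsample_bytree = config$colsample_bytree,
       nthread = 1L, seed = config$seed)
}

# Importance of every column for a fitted booster: total gain, 0 for unused.
booster_importance <- function(bst, feature_names) {
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0L) {
    gain[imp$Feature] <- imp$Gain
  }
  gain
}

#' Recursive feature elimination to a fixed budget
#'
#' Repeatedly fits the gradient-boosted estimator on the surviving columns,
#' ranks them by total gain, and removes the lowest-ranked `step` fraction
#' until `budget` columns remain (the final step is truncated to land exactly
#' on the budget). Features never used by any tree are eliminated first, in
#' stable column order.
#'
#' @param x a `feature_matrix` (training rows only).
#' @param labels binary labels.
#' @param budget number of features to retain.
#' @param config a [booster_config()] for the estimator.
#' @param step fraction of current columns removed per iteration (default
#'   0.05, at least one column).
#' @return a `selection_mask`: list with `features` (retained column names),
#'   `families`, `stage_log` and `elimination_order`.
#' @export
rfe <- function(x, labels, budget, config = booster_config(), step = 0.05) {
  if (budget <= 0L) stop("RFE budget must be positive", call. = FALSE)
  vals <- unclass(x)
  eliminated <- character(0)
  while (ncol(vals) > budget) {
    dm <- xgboost::xgb.DMatrix(vals, label = labels)
    bst <- xgboost::xgb.train(params = xgb_params(config), data = dm,
                              nrounds = config$n_trees, verbose = 0)
    gain <- booster_importance(bst, colnames(vals))
    n_drop <- max(1L, floor(step * ncol(vals)))
    n_drop <- min(n_drop, ncol(vals) - budget)
    # stable order: by gain ascending, ties by column position
    ord <- order(gain, seq_along(gain))
    drop_names <- colnames(vals)[ord[seq_len(n_drop)]]
    eliminated <- c(eliminated, drop_names)
    keepers <- setdiff(colnames(vals), drop_names)
    vals <- vals[, keepers, drop = FALSE]
  }
  retained <- colnames(vals)
  fam <- feature_families(x)[match(retained, colnames(x))]
  structure(list(features = retained, families = fam,
                 elimination_order = eliminated),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  fam <- table(x$families)
  cat(sprintf("<selection_mask> %d features (%s)\n", length(x$features),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
  invisible(x)
}

#' Full feature-selection pipeline for one training fold
#'
#' Applies, in order, the target-frequency filter, the correlation filter and
#' RFE, recording per-stage column counts. The feature budget follows the
#' number of feature families present: 400 for three or more, 300 for two,
#' 200 for one (unless `budget` is given).
#'
#' @param x a `feature_matrix` of training-fold rows.
#' @param labels binary labels for those rows.
#' @param budget feature budget; `NULL` = by family count (400/300/200).
#' @param min_count,threshold,step stage parameters (see the stage functions).
#' @param config booster configuration for the RFE estimator.
#' @return a `selection_mask` with a `stage_log` attribute-style entry.
#' @export
select_features <- function(x, labels, budget = NULL, min_count = 2L,
                            threshold = 0.8, step = 0.05,
                            config = booster_config()) {
  n_fam <- length(unique(feature_families(x)))
  if (is.null(budget)) {
    budget <- if (n_fam >= 3L) 400L else if (n_fam == 2L) 300L else 200L
  }
  log <- data.frame(stage = "input", n_features = ncol(x))
  x1 <- filter_target_frequency(x, min_count)
  log <- rbind(log, data.frame(stage = "target_frequency", n_features = ncol(x1)))
  x2 <- correlation_filter(x1, threshold)
  log <- rbind(log, data.frame(stage = "correlation", n_features = ncol(x2)))
  mask <- if (ncol(x2) <= budget) {
    structure(list(features = colnames(x2), families = feature_families(x2),
                   elimination_order = character(0)),
              class = "selection_mask")
  } else {
    rfe(x2, labels, budget, config = config, step = step)
  }
  log <- rbind(log, data.frame(stage = "rfe", n_features = length(mask$features)))
  mask$stage_log <- log
  mask
}

#' Apply a selection mask to a feature matrix
#'
#' @param mask a `selection_mask`.
#' @param x a `feature_matrix` containing the mask's features.
#' @return the reduced `feature_matrix` in mask order.
#' @export
apply_mask <- function(mask, x) {
  miss <- setdiff(mask$features, colnames(x))
  if (length(miss) > 0L) {
    stop("Mask features missing from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  fm_select(x, mask$features)
}
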