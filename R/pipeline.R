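# End-to-end orchestration: per-fold feature construction (fold-specific
# embedding network, train-fitted scaler and vocabulary), nested
# cross-validation, final-model fitting on the full training set, the
# shuffled-label control, and scoring of external libraries.

#' Pipeline configuration
#'
#' Bundles the knobs shared by [nested_cv()], [fit_final()] and
#' [shuffle_control()].
#'
#' @param families feature families to build (subset of `GNN`, `DESCRIPTOR`,
#'   `TARGET`, `FINGERPRINT`).
#' @param nbits,radius fingerprint folding length and radius.
#' @param budget RFE feature budget (`NULL` = 400/300/200 by family count).
#' @param rfe_step RFE per-iteration removal fraction.
#' @param gnn an [mpnn_config()] for the embedding network.
#' @param tune_iter booster tuning iterations (0 = skip tuning and use
#'   `booster`).
#' @param inner_k inner folds for booster tuning.
#' @param booster fallback/default [booster_config()].
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(families = c("GNN", "DESCRIPTOR", "TARGET"),
                            nbits = 2048L, radius = 2L, budget = NULL,
                            rfe_step = 0.05, gnn = mpnn_config(),
                            tune_iter = 15L, inner_k = 3L,
                            booster = booster_config(), seed = 1L) {
  stopifnot(all(families %in% FEATURE_FAMILIES))
  structure(list(families = families, nbits = nbits, radius = radius,
                 budget = budget, rfe_step = rfe_step, gnn = gnn,
                 tune_iter = tune_iter, inner_k = inner_k, booster = booster,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# One-off molecular computations shared by every fold.
precompute_features <- function(records, config) {
  graphs <- lapply(records$smiles_std, parse_smiles)
  out <- list(graphs = graphs)
  if ("DESCRIPTOR" %in% config$families) {
    out$descriptors <- compute_descriptors(records)
  }
  if ("FINGERPRINT" %in% config$families || "GNN" %in% config$families) {
    out$fingerprints <- fingerprint_matrix(records, radius = config$radius,
                                           nbits = config$nbits)
  }
  out
}

# Assemble the feature matrix for all records, with every train-derived
# statistic (encoder, scaler, vocabulary) fitted on `fit_idx` rows only.
# `labels` are used solely for training the embedding network.
build_fold_features <- function(records, pre, fit_idx, labels, config,
                                seed = config$seed) {
  parts <- list()
  artifacts <- list()
  if ("GNN" %in% config$families) {
    sub <- murcko_scaffold_split(records[fit_idx, , drop = FALSE], seed = seed)
    y_fit <- labels[fit_idx]
    ok <- length(sub$val) > 0L &&
      length(unique(y_fit[sub$train])) == 2L &&
      length(unique(y_fit[sub$val])) == 2L
    if (!ok) {
      # scaffold bins left a single-class validation part (rare actives can
      # concentrate in one bin); fall back to a stratified random 90/10 split
      rng <- local_rng(seed)
      val <- unlist(lapply(unique(y_fit), function(cl) {
        pool <- which(y_fit == cl)
        pool[sample_local(rng, length(pool),
                          max(1L, round(0.1 * length(pool))))]
      }))
      sub <- list(train = setdiff(seq_along(fit_idx), val), val = val)
    }
    gtr <- fit_idx[sub$train]
    gval <- fit_idx[sub$val]
    gcfg <- config$gnn
    gcfg$seed <- as.integer(seed)
    enc <- train_mpnn(pre$graphs, labels, gtr, gval, gcfg)
    parts$GNN <- extract_embeddings(enc, pre$graphs, ids = records$id)
    artifacts$encoder <- enc
  }
  if ("DESCRIPTOR" %in% config$families) {
    scaler <- fit_scaler(pre$descriptors, fit_idx)
    parts$DESCRIPTOR <- apply_scaler(scaler, pre$descriptors)
    artifacts$scaler <- scaler
  }
  if ("TARGET" %in% config$families) {
    vocab <- build_target_vocabulary(records[fit_idx, , drop = FALSE])
    parts$TARGET <- encode_targets(records, vocab)
    artifacts$vocabulary <- vocab
  }
  if ("FINGERPRINT" %in% config$families) {
    parts$FINGERPRINT <- pre$fingerprints
  }
  feats <- assemble_features(unname(parts[order(match(names(parts),
                                                      FEATURE_FAMILIES))]))
  list(features = feats, artifacts = artifacts)
}

# Train selection + booster on fit rows; return mask, config, model, and an
# evaluation on eval rows.
train_fold_model <- function(feats, labels, fit_idx, eval_idx, groups, config,
                             seed = config$seed) {
  x_fit <- fm_rows(feats, fit_idx)
  y_fit <- labels[fit_idx]
  mask <- select_features(x_fit, y_fit, budget = config$budget,
                          step = config$rfe_step,
                          config = replace_seed(config$booster, seed))
  x_sel <- apply_mask(mask, x_fit)
  bcfg <- if (config$tune_iter > 0L) {
    tune_booster(x_sel, y_fit, groups[fit_idx], n_iter = config$tune_iter,
                 inner_k = config$inner_k, seed = seed)$config
  } else {
    replace_seed(config$booster, seed)
  }
  model <- fit_booster(x_sel, y_fit, bcfg)
  report <- NULL
  if (length(eval_idx) > 0L) {
    p <- predict_booster(model, apply_mask(mask, fm_rows(feats, eval_idx)))
    report <- evaluate(p, labels[eval_idx])
  }
  list(mask = mask, config = bcfg, model = model, report = report)
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' Nested cross-validation over cluster-grouped outer folds
#'
#' For every outer fold: a fold-specific embedding network is trained on the
#' fold's training part only (scaffold-split internally), features are
#' assembled with train-fitted scaler and vocabulary, feature selection and
#' booster tuning run on the training part, and the fitted booster is
#' evaluated on the fold's validation part. Test rows of the plan are never
#' touched.
#'
#' @param records a labelled `compound_set`.
#' @param plan a `split_plan` from [build_split_plan()].
#' @param config a [pipeline_config()].
#' @return list with per-fold `reports`, `configs`, `masks`, and a `summary`
#'   data.frame of fold metrics.
#' @export
nested_cv <- function(records, plan, config = pipeline_config()) {
  audit_split_plan(plan)
  pre <- precompute_features(records, config)
  labels <- records$label
  groups <- plan$assignment$cluster
  reports <- list(); configs <- list(); masks <- list()
  for (f in seq_along(plan$outer_folds)) {
    fold <- plan$outer_folds[[f]]
    seed_f <- config$seed + f
    ff <- build_fold_features(records, pre, fold$train, labels, config,
                              seed = seed_f)
    res <- train_fold_model(ff$features, labels, fold$train, fold$val,
                            groups, config, seed = seed_f)
    reports[[f]] <- res$report
    configs[[f]] <- res$config
    masks[[f]] <- res$mask
  }
  summary <- do.call(rbind, lapply(seq_along(reports), function(f) {
    r <- reports[[f]]
    data.frame(fold = f, roc_auc = r$roc_auc, mcc = r$mcc, f1 = r$f1,
               balanced_accuracy = r$balanced_accuracy,
               precision = r$precision)
  }))
  list(reports = reports, configs = configs, masks = masks, summary = summary)
}

#' Train the final model and evaluate once on the held-out test set
#'
#' The booster uses the component-wise median of the outer-fold
#' hyperparameters; the embedding network, scaler, vocabulary and feature
#' selection are re-fitted on the full training set. The test rows enter no
#' fitting step and are scored exactly once.
#'
#' @param records a labelled `compound_set`.
#' @param plan a `split_plan`.
#' @param fold_configs list of per-fold [booster_config()]s from
#'   [nested_cv()] (`NULL` = use `config$booster`).
#' @param config a [pipeline_config()].
#' @return list with `bundle` (a `model_bundle` able to score new compounds)
#'   and `report` (test-set `eval_report`).
#' @export
fit_final <- function(records, plan, fold_configs = NULL,
                      config = pipeline_config()) {
  audit_split_plan(plan)
  pre <- precompute_features(records, config)
  labels <- records$label
  bcfg <- if (!is.null(fold_configs) && length(fold_configs) > 0L) {
    median_config(fold_configs, seed = config$seed)
  } else {
    config$booster
  }
  cfg <- config
  cfg$tune_iter <- 0L
  cfg$booster <- bcfg
  ff <- build_fold_features(records, pre, plan$train_idx, labels, cfg,
                            seed = config$seed)
  res <- train_fold_model(ff$features, labels, plan$train_idx, plan$test_idx,
                          plan$assignment$cluster, cfg, seed = config$seed)
  bundle <- structure(list(
    encoder = ff$artifacts$encoder, scaler = ff$artifacts$scaler,
    vocabulary = ff$artifacts$vocabulary, mask = res$mask,
    booster = res$model, booster_config = bcfg, families = config$families,
    nbits = config$nbits, radius = config$radius, seed = config$seed,
    train_smiles = records$smiles_std[plan$train_idx],
    train_active_smiles = records$smiles_std[plan$train_idx][
      labels[plan$train_idx] == 1]),
    class = "model_bundle")
  list(bundle = bundle, report = res$report)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> families: %s | %d selected features | seed %d\n",
              paste(x$families, collapse = "+"), length(x$mask$features),
              x$seed))
  invisible(x)
}

#' Shuffled-label control
#'
#' Permutes the training labels (seeded) and reruns the entire pipeline -
#' embedding network, feature selection and booster - on the shuffled data;
#' the test labels are untouched and used only for the final evaluation. A
#' sound pipeline scores at chance level here.
#'
#' @param records a labelled `compound_set`.
#' @param plan a `split_plan`.
#' @param config a [pipeline_config()]; tuning is skipped (the control uses
#'   `config$booster`).
#' @param seed permutation seed (defaults to `config$seed`).
#' @return the test-set `eval_report` of the control model.
#' @export
shuffle_control <- function(records, plan, config = pipeline_config(),
                            seed = config$seed) {
  audit_split_plan(plan)
  labels <- records$label
  shuffled <- labels
  rng <- local_rng(seed)
  shuffled[plan$train_idx] <- labels[plan$train_idx][
    sample_local(rng, seq_along(plan$train_idx))]
  stopifnot(identical(shuffled[plan$test_idx], labels[plan$test_idx]))
  recs <- records
  recs$label <- shuffled
  cfg <- config
  cfg$tune_iter <- 0L
  pre <- precompute_features(recs, cfg)
  ff <- build_fold_features(recs, pre, plan$train_idx, shuffled, cfg,
                            seed = seed)
  res <- train_fold_model(ff$features, shuffled, plan$train_idx,
                          plan$test_idx, plan$assignment$cluster, cfg,
                          seed = seed)
  res$report
}

#' Score new compounds with a fitted model bundle
#'
#' Rebuilds the bundle's feature families for the library (embeddings from
#' the bundle's encoder, descriptors through the bundle's scaler, target
#' annotations against the training vocabulary - unseen annotations are
#' ignored and missing ones give zero rows), applies the selection mask and
#' returns booster probabilities. Compounds whose standardized SMILES occurs
#' in the bundle's training set should be removed beforehand via
#' [deduplicate()].
#'
#' @param bundle a `model_bundle` from [fit_final()].
#' @param library a standardized `compound_set`.
#' @return numeric vector of predicted activity probabilities (named by id).
#' @export
predict_library <- function(bundle, library) {
  parts <- list()
  graphs <- lapply(library$smiles_std, parse_smiles)
  if ("GNN" %in% bundle$families) {
    parts$GNN <- extract_embeddings(bundle$encoder, graphs, ids = library$id)
  }
  if ("DESCRIPTOR" %in% bundle$families) {
    parts$DESCRIPTOR <- apply_scaler(bundle$scaler,
                                     compute_descriptors(library))
  }
  if ("TARGET" %in% bundle$families) {
    parts$TARGET <- encode_targets(library, bundle$vocabulary)
  }
  if ("FINGERPRINT" %in% bundle$families) {
    parts$FINGERPRINT <- fingerprint_matrix(library, radius = bundle$radius,
                                            nbits = bundle$nbits)
  }
  feats <- assemble_features(unname(parts[order(match(names(parts),
                                                      FEATURE_FAMILIES))]))
  p <- predict_booster(bundle$booster, apply_mask(bundle$mask, feats))
  stats::setNames(p, library$id)
}
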