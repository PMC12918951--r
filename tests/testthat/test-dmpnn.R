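# Directed message passing: structure, recurrence, readout, training.

incoming_count <- function(st, e) {
  # qualifying incoming edges of e under the reverse-edge exclusion
  sum(st$dst == st$src[e]) - as.integer(st$dst[st$rev[e]] == st$src[e])
}

test_that("directed-edge structure implements reverse-edge exclusion", {
  eth <- build_directed_graph(parse_smiles("CC"))
  expect_length(eth$src, 2L)
  expect_equal(vapply(1:2, incoming_count, integer(1), st = eth), c(0L, 0L))

  prop <- build_directed_graph(parse_smiles("CCC"))
  counts <- vapply(seq_along(prop$src), incoming_count, integer(1), st = prop)
  # edges leaving the middle atom receive exactly one incoming message
  expect_equal(sort(counts), c(0L, 0L, 1L, 1L))

  benz <- build_directed_graph(parse_smiles("c1ccccc1"))
  counts_b <- vapply(seq_along(benz$src), incoming_count, integer(1), st = benz)
  expect_true(all(counts_b == 1L))
})

test_that("message passing follows the recurrence", {
  cfg <- mpnn_config(depth = 3, hidden = 4, ffn_hidden = 3, ffn_layers = 1,
                     dropout = 0, seed = 1)
  w <- local({ set.seed(1); tdpscreen:::mpnn_init(cfg) })
  # ethane: no qualifying incoming edges, so hidden states never change
  bat <- tdpscreen:::batch_structures(list(build_directed_graph(parse_smiles("CC"))))
  fw <- tdpscreen:::mpnn_forward(w, bat, cfg, keep_cache = TRUE)
  expect_equal(fw$cache$H[[1]], fw$cache$H[[3]])
  # zero message weights freeze the states everywhere
  w0 <- w; w0$W_msg[] <- 0
  bat2 <- tdpscreen:::batch_structures(list(build_directed_graph(parse_smiles("CCO"))))
  fw2 <- tdpscreen:::mpnn_forward(w0, bat2, cfg, keep_cache = TRUE)
  expect_equal(fw2$cache$H[[1]], fw2$cache$H[[3]])
})

test_that("hand-unrolled recurrence matches on a three-atom path", {
  # hidden dim 1, hand-set weights; recompute the forward pass from the
  # definitions with plain loops and compare
  cfg <- mpnn_config(depth = 3, hidden = 1, ffn_hidden = 1, ffn_layers = 1,
                     dropout = 0, seed = 1)
  g <- parse_smiles("CCO")
  st <- build_directed_graph(g)
  w <- tdpscreen:::mpnn_init(cfg)
  w$W_in <- matrix(seq(0.01, by = 0.01,
                       length.out = nrow(w$W_in)), ncol = 1)
  w$W_msg <- matrix(0.5, 1, 1)
  bat <- tdpscreen:::batch_structures(list(st))
  fw <- tdpscreen:::mpnn_forward(w, bat, cfg, keep_cache = TRUE)
  h0 <- pmax(0, bat$xe %*% w$W_in)
  h <- h0
  for (t in 1:2) {
    m <- numeric(length(st$src))
    for (e in seq_along(st$src)) {
      for (e2 in seq_along(st$src)) {
        if (st$dst[e2] == st$src[e] && e2 != st$rev[e]) m[e] <- m[e] + h[e2]
      }
    }
    h <- pmax(0, h0 + m * 0.5)
  }
  expect_equal(unname(as.vector(fw$cache$H[[3]])), unname(as.vector(h)),
               tolerance = 1e-12)
})

test_that("readout is permutation invariant and mean-aggregated", {
  cfg <- mpnn_config(depth = 2, hidden = 8, seed = 2)
  w <- local({ set.seed(2); tdpscreen:::mpnn_init(cfg) })
  embed <- function(s) {
    bat <- tdpscreen:::batch_structures(list(build_directed_graph(parse_smiles(s))))
    tdpscreen:::mpnn_forward(w, bat, cfg)$Z
  }
  expect_lt(max(abs(embed("OCC") - embed("CCO"))), 1e-6)
  # two disconnected copies of a fragment equal one copy (mean aggregation)
  expect_lt(max(abs(embed("CCO.CCO") - embed("CCO"))), 1e-6)
  # single heavy atom: embedding = relu(W_atom [x ; 0])
  batm <- tdpscreen:::batch_structures(list(build_directed_graph(parse_smiles("C"))))
  zm <- tdpscreen:::mpnn_forward(w, batm, cfg)$Z
  xa <- tdpscreen:::atom_features(parse_smiles("C")$atoms)
  manual <- pmax(0, cbind(xa, matrix(0, 1, 8)) %*% w$W_atom)
  expect_equal(as.vector(zm), as.vector(manual), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  graphs <- lapply(c("CCO", "c1ccc2ncccc2c1", "CC(=O)O", "C1CCCCC1"),
                   parse_smiles)
  y <- c(1, 1, 0, 0)
  cfg <- mpnn_config(depth = 3, hidden = 5, ffn_hidden = 4, ffn_layers = 2,
                     dropout = 0, seed = 3)
  w <- local({ set.seed(3); tdpscreen:::mpnn_init(cfg) })
  bat <- tdpscreen:::batch_structures(lapply(graphs, build_directed_graph))
  lossfun <- function(w) {
    fw <- tdpscreen:::mpnn_forward(w, bat, cfg)
    tdpscreen:::weighted_bce(fw$logit, y, 2)
  }
  fw <- tdpscreen:::mpnn_forward(w, bat, cfg, keep_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logit))
  wts <- ifelse(y == 1, 2, 1)
  g <- tdpscreen:::mpnn_backward(w, bat, cfg, fw$cache,
                                 matrix(wts * (p - y) / sum(wts), ncol = 1))
  eps <- 1e-6
  for (nm in names(g)) {
    idx <- if (length(w[[nm]]) > 4) sample(length(w[[nm]]), 4) else
      seq_along(w[[nm]])
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-5)
    }
  }
})

test_that("training recovers a strong planted signal and is deterministic", {
  ds <- generate_dataset(synth_config(n = 800, p_active_motif = 0.95,
                                      p_active_nomotif = 0.01, seed = 11))
  graphs <- lapply(ds$smiles_std, parse_smiles)
  set.seed(4); idx <- sample(800)
  tr <- idx[1:600]; va <- idx[601:800]
  m <- train_mpnn(graphs, ds$label, tr, va, mpnn_config(seed = 4))
  expect_gt(roc_auc(predict_mpnn(m, graphs[va]), ds$label[va]), 0.9)
  expect_lte(nrow(m$history), m$config$max_epochs)
  expect_equal(min(m$history$val_loss),
               m$history$val_loss[m$best_epoch])
  # identical seeds give identical weights
  m2 <- train_mpnn(graphs, ds$label, tr, va, mpnn_config(seed = 4))
  expect_identical(m$weights, m2$weights)
  # labels without structure -> chance-level validation AUC
  set.seed(123); rl <- rbinom(800, 1, 0.5)
  m0 <- train_mpnn(graphs, rl, tr, va, mpnn_config(seed = 4))
  auc0 <- roc_auc(predict_mpnn(m0, graphs[va]), rl[va])
  expect_gt(auc0, 0.4); expect_lt(auc0, 0.6)
  expect_error(train_mpnn(graphs, rep(1, 800), tr, va, mpnn_config()),
               "both classes")
})

test_that("random-search tuning honours the argmin contract", {
  ds <- generate_dataset(synth_config(n = 120, seed = 17))
  graphs <- lapply(ds$smiles_std, parse_smiles)
  set.seed(8); idx <- sample(120)
  tr <- idx[1:90]; va <- idx[91:120]
  tuned <- tune_mpnn(graphs, ds$label, tr, va, n_trials = 3L, seed = 8,
                     scale = 0.05, max_epochs = 2L)
  expect_equal(nrow(tuned$trials), 3L)
  best_row <- tuned$trials[which.min(tuned$trials$val_loss), ]
  expect_equal(tuned$config$depth, best_row$depth)
  expect_equal(tuned$config$hidden, best_row$hidden)
  tuned2 <- tune_mpnn(graphs, ds$label, tr, va, n_trials = 3L, seed = 8,
                      scale = 0.05, max_epochs = 2L)
  expect_identical(tuned$trials, tuned2$trials)
  one <- tune_mpnn(graphs, ds$label, tr, va, n_trials = 1L, seed = 9,
                   scale = 0.05, max_epochs = 2L)
  expect_equal(nrow(one$trials), 1L)
})

test_that("embedding extraction is deterministic with the right shape", {
  ds <- generate_dataset(synth_config(n = 80, seed = 24))
  graphs <- lapply(ds$smiles_std, parse_smiles)
  pos <- which(ds$label == 1); neg <- which(ds$label == 0)
  tr <- c(pos[-(1:2)], neg[-(1:10)]); va <- c(pos[1:2], neg[1:10])
  m <- train_mpnn(graphs, ds$label, tr, va,
                  mpnn_config(max_epochs = 2L, seed = 5))
  emb <- extract_embeddings(m, graphs, ids = ds$id)
  expect_equal(dim(emb), c(80L, 64L))
  expect_identical(feature_families(emb), rep("GNN", 64L))
  emb2 <- extract_embeddings(m, graphs, ids = ds$id)
  expect_identical(unclass(emb), unclass(emb2))
  # duplicated molecule gives identical rows
  emb3 <- extract_embeddings(m, graphs[c(1, 1)], ids = c("a", "b"))
  expect_equal(unname(unclass(emb3)[1, ]), unname(unclass(emb3)[2, ]))
})
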