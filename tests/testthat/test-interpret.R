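# Shapley attributions, feature ranking, correlations, rationales, t-SNE.

fit_toy_booster <- function(n = 80, p = 4, seed = 2, trees = 15, depth = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(x[, 1] - 0.7 * x[, 2] + rnorm(n, 0, 0.4) > 0)
  fmx <- feature_matrix(x, "DESCRIPTOR")
  list(x = fmx, y = y,
       model = fit_booster(fmx, y, booster_config(n_trees = trees,
                                                  max_depth = depth,
                                                  seed = seed)))
}

test_that("Shapley attributions satisfy local accuracy to 1e-6", {
  toy <- fit_toy_booster()
  at <- shapley_attributions(toy$model, toy$x)
  margin <- tdpscreen:::booster_margin(toy$model, unclass(toy$x))
  expect_lt(max(abs(rowSums(at$values) + at$base - margin)), 1e-6)
  # and the double-precision margin agrees with the library's evaluation
  lib_margin <- stats::predict(toy$model$booster, unclass(toy$x),
                               outputmargin = TRUE)
  expect_lt(max(abs(margin - lib_margin)), 1e-5)
})

test_that("Shapley values equal brute-force subset enumeration", {
  toy <- fit_toy_booster(n = 60, p = 3, trees = 8, depth = 3)
  trees <- tdpscreen:::parse_booster_trees(toy$model)
  expvalue <- function(tree, x, S, node = 1L) {
    if (tree$leaf[node]) return(tree$value[node])
    f <- tree$feature[node]
    if (f %in% S) {
      nxt <- if (x[f] < tree$split[node]) tree$yes[node] else tree$no[node]
      return(expvalue(tree, x, S, nxt))
    }
    wy <- tree$cover[tree$yes[node]]; wn <- tree$cover[tree$no[node]]
    (wy * expvalue(tree, x, S, tree$yes[node]) +
       wn * expvalue(tree, x, S, tree$no[node])) / (wy + wn)
  }
  brute <- function(x, p) {
    phi <- numeric(p)
    subsets <- lapply(0:(2^p - 1),
                      function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
    for (i in seq_len(p)) for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      for (tr in trees) {
        phi[i] <- phi[i] + w * (expvalue(tr, x, c(S, i)) - expvalue(tr, x, S))
      }
    }
    phi
  }
  at <- shapley_attributions(toy$model, toy$x)
  for (r in 1:8) {
    xr <- tdpscreen:::as_float32(unclass(toy$x)[r, ])
    expect_equal(unname(at$values[r, ]), brute(xr, 3), tolerance = 1e-6)
  }
  # the library's own (single-precision) contributions agree closely
  contrib <- stats::predict(toy$model$booster, unclass(toy$x),
                            predcontrib = TRUE)
  expect_lt(max(abs(at$values - contrib[, 1:3])), 1e-4)
})

test_that("unused features get zero attribution and rank last", {
  toy <- fit_toy_booster(n = 100, p = 5, trees = 10, depth = 2)
  at <- shapley_attributions(toy$model, toy$x)
  used <- unique(unlist(lapply(tdpscreen:::parse_booster_trees(toy$model),
                               function(tr) tr$feature)))
  unused <- setdiff(seq_len(5), used[!is.na(used)])
  if (length(unused) > 0) {
    expect_equal(sum(abs(at$values[, unused])), 0)
    rk <- rank_features(at, top_k = 5)
    expect_true(all(colnames(at$values)[unused] %in%
                      utils::tail(rk$feature, length(unused))))
  }
  rk_all <- rank_features(at, top_k = 100)
  expect_equal(nrow(rk_all), 5L)                       # capped at p
  expect_true(!is.unsorted(rev(rk_all$mean_abs_shap)))
  expect_true(!is.null(attr(rk_all, "beeswarm")))
})

test_that("target-descriptor correlation is symmetric with flagged constants", {
  set.seed(8)
  n <- 400
  d <- rnorm(n)
  m <- cbind(t1 = as.integer(d > 0.5), t2 = rbinom(n, 1, 0.3),
             tconst = rep(0, n), d1 = d, d2 = rnorm(n))
  fmx <- feature_matrix(m, c("TARGET", "TARGET", "TARGET", "DESCRIPTOR",
                             "DESCRIPTOR"))
  tab <- target_descriptor_correlation(fmx)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$constant[tab$target == "tconst"]))
  expect_equal(tab$r[tab$target == "tconst"], c(0, 0))
  # independent columns: weak correlation
  expect_lt(abs(tab$r[tab$target == "t2" & tab$descriptor == "d2"]), 0.15)
  # binarized copy of a descriptor correlates strongly
  expect_gt(tab$r[tab$target == "t1" & tab$descriptor == "d1"], 0.5)
  # symmetry under role exchange
  r1 <- tab$r[tab$target == "t2" & tab$descriptor == "d1"]
  expect_equal(r1, stats::cor(m[, "t2"], m[, "d1"]))
})

test_that("rationale search respects its boundary conditions", {
  final <- fixture_final()
  enc <- final$bundle$encoder
  ds <- fixture_dataset()
  g <- parse_smiles(ds$smiles_std[[1]])
  expect_equal(nrow(mcts_rationale(enc, g, n_rollouts = 0L)), 0L)
  expect_warning(
    out <- mcts_rationale(enc, parse_smiles("CCO"), min_atoms = 8L),
    "smaller")
  expect_equal(nrow(out), 0L)
  # a molecule of exactly min_atoms can only return itself
  small <- parse_smiles("c1ccc2ncccc2c1")
  res <- mcts_rationale(enc, small, min_atoms = 10L, max_atoms = 20L,
                        n_rollouts = 5L, seed = 1)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_atoms, 10L)
})

test_that("rationales are connected valid molecules that recover the motif", {
  final <- fixture_final()
  enc <- final$bundle$encoder
  ds <- fixture_dataset()
  plan <- fixture_plan()
  cand <- which(seq_len(nrow(ds)) %in% plan$test_idx &
                  ds$label == 1 & ds$motif)
  cand <- utils::head(cand, 10)
  hits <- 0; tot <- 0
  for (i in cand) {
    g <- parse_smiles(ds$smiles_std[i])
    rat <- mcts_rationale(enc, g, min_atoms = 8L, max_atoms = 20L,
                          n_rollouts = 60L, seed = 7, top_k = 1L)
    if (nrow(rat) == 0L) next
    tot <- tot + 1
    # valid, connected molecule after hydrogen patching
    gg <- parse_smiles(rat$smiles[1])
    expect_equal(max(tdpscreen:::graph_components(gg)), 1L)
    expect_false(is.na(ob_canonical(rat$smiles[1])))
    cnt <- tdpscreen:::ob_smarts_count(tdpscreen:::ob_sdfset(rat$smiles[1]),
                                       tdpscreen:::MOTIF_SMARTS_DEFAULT, 1L)
    if (!is.na(cnt) && cnt > 0) hits <- hits + 1
  }
  expect_gte(tot, 5)
  expect_gte(hits / tot, 0.8)
})

test_that("t-SNE separates distinct chemical families and is reproducible", {
  # two structurally homogeneous families: decorated quinolines vs decorated
  # cyclohexanes
  recs <- generate_molecules(synth_config(n = 800, seed = 33))
  scaf <- vapply(recs$smiles_std, murcko_scaffold, character(1))
  hex_scaf <- murcko_scaffold("C1CCCCC1C")
  idx <- c(utils::head(which(recs$motif), 50),
           utils::head(which(scaf == hex_scaf), 37))
  fps <- unclass(fingerprint_matrix(recs[idx, , drop = FALSE], nbits = 256L))
  fam <- rep(c("quinoline", "cyclohexane"), c(50, length(idx) - 50))
  expect_warning(
    m1 <- chemical_space_map(fps, perplexity = 50, seed = 4, class = fam),
    "Perplexity reduced")
  m2 <- suppressWarnings(chemical_space_map(fps, perplexity = 50, seed = 4,
                                            class = fam))
  expect_equal(m1$x, m2$x)
  xy <- cbind(m1$x, m1$y)
  # duplicated fingerprints land together
  dup <- which(duplicated(fps) | duplicated(fps, fromLast = TRUE))
  pair <- which(apply(fps, 1, paste, collapse = "") ==
                  paste(fps[dup[1], ], collapse = ""))[1:2]
  dd <- sqrt(sum((xy[pair[1], ] - xy[pair[2], ])^2))
  spread <- stats::sd(m1$x) + stats::sd(m1$y)
  expect_lt(dd, 0.1 * spread)
  # silhouette of the 2-D embedding for the two families
  D <- as.matrix(stats::dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- fam == fam[i]; own[i] <- FALSE
    a <- mean(D[i, own]); b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.3)
})
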