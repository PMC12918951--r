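# Butina clustering, cluster-respecting splits, grouped folds and scaffold
# splits.

test_that("butina clustering matches the sphere-exclusion rules", {
  # all pairwise distances above the cutoff -> singletons
  fps <- diag(1, 4)
  as1 <- butina_cluster(fps, 0.4)
  expect_equal(length(as1$members), 4L)
  # two identical molecules plus one distant -> {1,2},{3}
  fps2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  as2 <- butina_cluster(fps2, 0.4)
  expect_equal(as2$cluster[1], as2$cluster[2])
  expect_false(as2$cluster[1] == as2$cluster[3])
  expect_equal(butina_cluster(matrix(0, 0, 4), 0.4)$cluster, integer(0))
})

test_that("butina equals a brute-force oracle on small molecule sets", {
  corpus <- fixture_corpus(36, seed = 9)
  for (start in c(1, 13, 25)) {
    smiles <- corpus[start:(start + 11)]          # 12-molecule fixtures
    fps <- do.call(rbind, lapply(smiles, function(s)
      compute_ecfp(parse_smiles(s), nbits = 256L)))
    for (cutoff in c(0.3, 0.4, 0.6)) {
      mine <- butina_cluster(fps, cutoff)$cluster
      oracle <- brute_force_butina(fps, cutoff)
      expect_identical(mine, oracle)
    }
  }
})

test_that("cluster train/test split keeps clusters whole and classes balanced", {
  # singleton clusters split cleanly at the requested fraction
  fps <- diag(1, 10)
  as1 <- butina_cluster(fps, 0.2)
  plan <- cluster_train_test_split(as1, rep(c(0, 1), 5), 0.2, seed = 1)
  expect_equal(length(plan$test_idx), 2L)
  expect_equal(sort(c(plan$train_idx, plan$test_idx)), 1:10)

  ds <- fixture_dataset()
  plan2 <- fixture_plan()
  cl <- plan2$assignment$cluster
  expect_length(intersect(cl[plan2$train_idx], cl[plan2$test_idx]), 0L)
  expect_lt(abs(mean(ds$label[plan2$test_idx]) - mean(ds$label)), 0.03 + 1e-9)
  expect_error(cluster_train_test_split(
    butina_cluster(rbind(c(1, 0), c(1, 0)), 0.5), c(0, 1)), "single cluster")
})

test_that("stratified grouped folds keep groups whole and balance classes", {
  folds <- stratified_group_kfold(1:10, rep(c(0, 1), 5), 1:10, k = 5, seed = 2)
  for (f in folds) {
    expect_length(f$val, 2L)
    expect_equal(sum(rep(c(0, 1), 5)[f$val]), 1)
  }
  expect_error(stratified_group_kfold(1:4, c(0, 1, 0, 1), c(1, 1, 2, 2), k = 3),
               "at least 3 groups")

  ds <- fixture_dataset()
  fps <- unclass(fingerprint_matrix(ds, nbits = 256L))
  groups <- butina_cluster(fps, 0.4)$cluster
  folds2 <- stratified_group_kfold(seq_len(nrow(ds)), ds$label, groups,
                                   k = 5, seed = 2)
  val_groups <- lapply(folds2, function(f) unique(groups[f$val]))
  expect_false(anyDuplicated(unlist(val_groups)) > 0)
  covered <- sort(unlist(lapply(folds2, `[[`, "val")))
  expect_identical(covered, seq_len(nrow(ds)))
  devs <- vapply(folds2, function(f)
    abs(mean(ds$label[f$val]) - mean(ds$label)), numeric(1))
  expect_true(all(devs <= 0.05 + 1e-9))
})

test_that("scaffold split bins whole scaffolds and meets quotas", {
  # all molecules share a scaffold -> everything in train, warning emitted
  shared <- paste0("c1ccccc1", c("C", "CC", "CCC", "CCCC"))
  expect_warning(sp <- murcko_scaffold_split(standardize_smiles(shared)),
                 "empty partition")
  expect_length(sp$train, 4L)

  # acyclic molecules share the empty-scaffold bin
  expect_identical(murcko_scaffold("CCCCC"), "")
  expect_identical(murcko_scaffold("CC(C)CO"), "")

  corpus <- fixture_corpus(300, seed = 13)
  sp2 <- murcko_scaffold_split(corpus, seed = 1)
  scafs <- vapply(corpus, murcko_scaffold, character(1))
  for (part in sp2) {
    other <- setdiff(unlist(sp2), part)
    expect_length(intersect(scafs[part], scafs[other]), 0L)
  }
  expect_lt(abs(length(sp2$train) - 240), 300 * 0.1)
})

test_that("split plans are deterministic and leakage-free", {
  ds <- fixture_dataset()
  p1 <- build_split_plan(ds, k = 2L, nbits = 256L, seed = 3)
  p2 <- build_split_plan(ds, k = 2L, nbits = 256L, seed = 3)
  expect_identical(p1$train_idx, p2$train_idx)
  expect_identical(p1$outer_folds, p2$outer_folds)
  expect_true(audit_split_plan(p1))
  covered <- sort(unlist(lapply(p1$outer_folds, `[[`, "val")))
  expect_identical(covered, sort(p1$train_idx))
})
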