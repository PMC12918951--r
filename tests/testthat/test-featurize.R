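# Descriptors, fingerprints, target encoding, scaling and assembly.

test_that("descriptor worked examples and determinism", {
  d <- compute_descriptors("C")
  expect_equal(unname(d[["ExactMolWt"]]), 16.031, tolerance = 1e-3)
  expect_equal(unname(d[["MW"]]), 16.04, tolerance = 1e-2)
  b <- compute_descriptors("c1ccccc1")
  expect_equal(unname(b[["TPSA"]]), 0)
  expect_equal(unname(b[["NumAromaticRings"]]), 1)
  expect_identical(compute_descriptors("c1ccccc1"), b)
  # the interpretability-featured descriptor names are all present
  expect_true(all(c("MolLogP", "TPSA", "MW", "QED", "EState_VSA8",
                    "SMR_VSA9") %in% names(d)))
  expect_true(d[["QED"]] > 0 && d[["QED"]] < 1)
})

test_that("fingerprints: single-atom molecule, popcount bound, purity", {
  expect_equal(sum(compute_ecfp("C")), 1L)
  for (s in c("CCO", "c1ccc2ncccc2c1", "CC(=O)Nc1ccc(O)cc1")) {
    g <- parse_smiles(s)
    fp <- compute_ecfp(g)
    # folding can only merge identifiers: (atoms) x (radius + 1) is an upper
    # bound on the number of set bits
    expect_lte(sum(fp), nrow(g$atoms) * 3L)
    expect_identical(fp, compute_ecfp(parse_smiles(s)))
  }
  expect_error(compute_ecfp("C", nbits = 1000L), "power of two")
})

test_that("fingerprints match an independent reimplementation bit for bit", {
  corpus <- fixture_corpus(100)
  graphs <- lapply(corpus, parse_smiles)
  payload <- list(radius = 2L, nbits = 512L,
                  graphs = lapply(graphs, graph_to_json))
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, jf, auto_unbox = TRUE)
  oracle <- system2(python_binary(),
                    c(test_path("oracle_ecfp.py"), jf), stdout = TRUE)
  expect_length(oracle, 100L)
  for (k in seq_along(graphs)) {
    mine <- which(compute_ecfp(graphs[[k]], nbits = 512L) == 1L) - 1L
    theirs <- as.integer(strsplit(oracle[[k]], ",")[[1]])
    expect_identical(mine, theirs)
  }
})

test_that("tanimoto similarity follows the set-overlap definition", {
  expect_equal(tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 0)), "mismatch")
  # symmetry on random vectors
  set.seed(1)
  for (k in 1:10) {
    a <- rbinom(64, 1, 0.2); b <- rbinom(64, 1, 0.2)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("min-max scaler maps training rows into [0,1] and clips queries", {
  set.seed(7)
  m <- matrix(rnorm(60, sd = 5), 20, 3,
              dimnames = list(NULL, c("d1", "d2", "d3")))
  fmx <- feature_matrix(m, "DESCRIPTOR")
  sc <- fit_scaler(fmx, rows = 1:12)
  tr <- apply_scaler(sc, fmx)
  expect_true(all(unclass(tr)[1:12, ] >= 0 & unclass(tr)[1:12, ] <= 1))
  expect_true(all(unclass(tr) >= 0 & unclass(tr) <= 1))  # held-out clipped
  # degenerate column maps to 0
  m2 <- cbind(m, d4 = rep(2, 20))
  sc2 <- fit_scaler(feature_matrix(m2, "DESCRIPTOR"))
  out <- apply_scaler(sc2, feature_matrix(m2, "DESCRIPTOR"))
  expect_true(all(unclass(out)[, "d4"] == 0))
})

test_that("target encoding respects the training vocabulary", {
  ds <- make_compound_set(c("a", "b", "c"), c("CC", "CCC", "CCCC"),
                          targets = list(c("A", "B"), character(0), "Z"))
  enc <- encode_targets(ds, c("A", "B", "C"))
  expect_equal(unname(unclass(enc)["a", ]), c(1, 1, 0))
  expect_equal(unname(unclass(enc)["b", ]), c(0, 0, 0))
  expect_equal(unname(unclass(enc)["c", ]), c(0, 0, 0))  # Z not in vocab
  expect_identical(feature_families(enc), rep("TARGET", 3L))
})

test_that("feature assembly concatenates and validates", {
  a <- feature_matrix(matrix(1:4, 2, dimnames = list(c("x", "y"), c("f1", "f2"))),
                      "DESCRIPTOR")
  b <- feature_matrix(matrix(0:3, 2, dimnames = list(c("x", "y"), c("g1", "g2"))),
                      "TARGET")
  ab <- assemble_features(list(a, b))
  expect_equal(dim(ab), c(2L, 4L))
  expect_identical(feature_families(ab),
                   c("DESCRIPTOR", "DESCRIPTOR", "TARGET", "TARGET"))
  expect_identical(assemble_features(list(a)), a)
  bad <- feature_matrix(matrix(0:3, 2, dimnames = list(c("x", "z"), c("h1", "h2"))),
                        "TARGET")
  expect_error(assemble_features(list(a, bad)), "Row ids")
  dup <- feature_matrix(matrix(0:3, 2, dimnames = list(c("x", "y"), c("f1", "h2"))),
                        "TARGET")
  expect_error(assemble_features(list(a, dup)), "collision")
})
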