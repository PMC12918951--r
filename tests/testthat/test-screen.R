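# Library scoring, drug-likeness filters, alerts, novelty, cascade.

test_that("library prediction routes through the bundle and dedup", {
  final <- fixture_final()
  ds <- fixture_dataset()
  lib <- generate_screening_library(synth_config(n = 120, seed = 77))
  recs <- deduplicate(lib$records, ds)
  expect_false(any(recs$smiles_std %in% ds$smiles_std))
  # a training molecule sneaked into the library is removed by dedup
  sneak <- make_compound_set(c(recs$id, "sneak"),
                             c(recs$smiles_std, ds$smiles_std[1]))
  expect_false("sneak" %in% deduplicate(sneak, ds)$id)
  p <- predict_library(final$bundle, recs)
  expect_true(all(p >= 0 & p <= 1))
  info <- tdpscreen:::ob_sdfset(recs$smiles_std)
  motif <- tdpscreen:::ob_smarts_count(info, tdpscreen:::MOTIF_SMARTS_DEFAULT,
                                       nrow(recs)) > 0
  expect_gt(mean(p[motif]), mean(p[!motif]))
})

test_that("Rule-of-Five violation counts match hand computation", {
  expect_equal(lipinski_violations("C"), 0L)
  # a 60-carbon alkane: MW ~ 843 > 500 and logP far above 5 -> 2 violations
  alkane <- paste0(rep("C", 60), collapse = "")
  expect_equal(lipinski_violations(alkane), 2L)
  # berberrubine passes with zero violations
  berb <- standardize("COc1ccc2cc3[n+](cc2c1O)CCc1cc2c(cc1-3)OCO2")
  expect_equal(lipinski_violations(berb), 0L)
  # many donors/acceptors: a polyol chain with 12 hydroxyls
  polyol <- standardize("OCC(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)CO")
  expect_gte(lipinski_violations(polyol), 2L)
})

test_that("structural alerts match an independent substructure oracle", {
  pains <- load_alert_catalog(catalog_path("pains"))
  brenk <- load_alert_catalog(catalog_path("brenk"))
  expect_error(
    load_alert_catalog({
      tf <- tempfile(fileext = ".tsv")
      writeLines(c("name\tsmarts", "broken\t[C1("), tf)
      tf
    }), "broken")
  fixture <- c(
    "C", "CCO", "c1ccccc1", "O=C1C=CC(=O)C=C1", "Oc1ccc(O)cc1",
    "CC(=O)Cl", "CCCl", "CC(=O)C(=O)C", "C1OC1", "CSSC",
    "O=[N+]([O-])c1ccccc1", "NNc1ccccc1", "CC=O", "C=CC(=O)C=C",
    "c1ccc2ncccc2c1", "CC(C)(C)c1ccc(O)cc1", "N#CN", "CC(=O)OC",
    "S=C1NC(=O)CS1")
  fixture <- standardize_smiles(fixture)
  expect_false(anyNA(fixture))
  mine_p <- structural_alerts(unname(fixture), pains)
  mine_b <- structural_alerts(unname(fixture), brenk)

  # oracle: an independent toolkit's substructure matcher
  oracle_counts <- function(smiles, catalog) {
    script <- tempfile(fileext = ".py")
    writeLines(c(
      "import sys, json",
      "from rdkit import Chem",
      "payload = json.load(open(sys.argv[1]))",
      "pats = [(n, Chem.MolFromSmarts(s)) for n, s in payload['patterns']]",
      "for smi in payload['smiles']:",
      "    mol = Chem.MolFromSmiles(smi)",
      "    hits = 0 if mol is None else sum(",
      "        1 for _, p in pats if p is not None and mol.HasSubstructMatch(p))",
      "    print(hits)"), script)
    jf <- tempfile(fileext = ".json")
    jsonlite::write_json(
      list(patterns = lapply(seq_len(nrow(catalog)), function(k)
        list(catalog$name[k], catalog$smarts[k])),
        smiles = as.list(unname(smiles))), jf, auto_unbox = TRUE)
    as.integer(system2(python_binary(), c(script, jf), stdout = TRUE))
  }
  op <- tryCatch(oracle_counts(fixture, pains), warning = function(w) NULL,
                 error = function(e) NULL)
  if (!is.null(op) && length(op) == length(fixture)) {
    expect_equal(mine_p$n_alerts, op)
    expect_equal(mine_b$n_alerts, oracle_counts(fixture, brenk))
  } else {
    # fallback oracle: direct single-pattern matching through a second
    # OpenBabel entry point (obabel -s filter)
    for (k in c(1, 4, 6)) {
      pat <- brenk$smarts[k]
      tf <- tempfile(fileext = ".smi")
      writeLines(paste(fixture, seq_along(fixture)), tf)
      out <- suppressWarnings(system2(
        "obabel", c(shQuote(tf), "-osmi", paste0("-s", shQuote(pat)), "-e"),
        stdout = TRUE, stderr = FALSE))
      matched_idx <- as.integer(sub(".*\t", "", out[nzchar(out)]))
      mine_hits <- grepl(paste0("(^|;)", brenk$name[k], "(;|$)"),
                         mine_b$alerts)
      expect_setequal(which(mine_hits), matched_idx)
    }
  }
  expect_equal(mine_p$n_alerts[1], 0)                  # methane
  expect_gte(mine_p$n_alerts[4], 1)                    # quinone
  expect_true(grepl("quinone", mine_p$alerts[4]))
})

test_that("novelty is the exhaustive maximum Tanimoto to the references", {
  set.seed(12)
  refs <- matrix(rbinom(5 * 64, 1, 0.3), 5, 64)
  cands <- rbind(refs[2, ], matrix(rbinom(2 * 64, 1, 0.3), 2, 64))
  nv <- novelty(cands, refs)
  expect_equal(nv[1], 1)
  brute <- vapply(seq_len(nrow(cands)), function(i)
    max(vapply(seq_len(nrow(refs)), function(j)
      tanimoto(cands[i, ], refs[j, ]), numeric(1))), numeric(1))
  expect_equal(unname(nv), brute)
  disjoint <- matrix(0, 1, 64); disjoint[1, 1:5] <- 1
  refs0 <- matrix(0, 1, 64); refs0[1, 6:10] <- 1
  expect_equal(unname(novelty(disjoint, refs0)), 0)
  expect_error(novelty(cands, refs[0, , drop = FALSE]), "empty")
})

test_that("the filter cascade applies every criterion in order", {
  pains <- load_alert_catalog(catalog_path("pains"))
  brenk <- load_alert_catalog(catalog_path("brenk"))
  smiles <- c(
    good = "c1ccc2ncccc2c1",                       # passes everything
    lowp = "CCO",                                  # fails the threshold
    quin = "O=C1C=CC(=O)C=C1",                     # PAINS hit
    brnk2 = "O=[N+]([O-])c1ccc(C=O)cc1",           # two Brenk alerts
    fat = paste0(rep("C", 60), collapse = ""),     # Rule-of-Five failure
    nob = "c1cc2ncccc2cc1C",                       # fails BBB annotation
    prior = "c1cc2ncccc2cc1O")                     # previously tested
  recs <- make_compound_set(names(smiles), unname(smiles))
  probs <- stats::setNames(c(0.95, 0.79, 0.9, 0.9, 0.9, 0.9, 0.9), recs$id)
  ann <- data.frame(id = recs$id,
                    bbb = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                    prior_tested = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                     FALSE, TRUE))
  rep <- filter_cascade(probs, recs, ann, pains = pains, brenk = brenk)
  expect_identical(rep$id[rep$verdict], "good")
  expect_false(rep$pass_probability[rep$id == "lowp"])  # 0.79 fails strict >
  expect_false(rep$pass_pains[rep$id == "quin"])
  expect_false(rep$pass_brenk[rep$id == "brnk2"])
  expect_gte(rep$brenk_alerts[rep$id == "brnk2"], 2)
  expect_false(rep$pass_ro5[rep$id == "fat"])
  expect_false(rep$pass_bbb[rep$id == "nob"])
  expect_false(rep$pass_prior[rep$id == "prior"])
  # survivor log is monotone
  log <- stage_log(rep)
  expect_true(all(diff(log$survivors) <= 0))
  # re-running yields identical reports (pure function)
  rep2 <- filter_cascade(probs, recs, ann, pains = pains, brenk = brenk)
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
  # missing annotation columns skip those criteria with a warning
  w <- testthat::capture_warnings(
    rep3 <- filter_cascade(probs, recs, NULL, pains = pains, brenk = brenk))
  expect_true(any(grepl("SKIPPED", w)))
  expect_true(all(rep3$pass_bbb))
})
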