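# Virtual screening: library scoring, drug-likeness and structural-alert
# filtering, and novelty versus the training actives.
#
# The shipped alert catalogs (inst/extdata/*_alerts_subset.tsv) are curated
# subsets of the published PAINS and Brenk pattern sets, rewritten as
# OpenBabel-compatible SMARTS; custom catalogs in the same two-column format
# can be supplied instead.

#' Load a SMARTS alert catalog
#'
#' Reads a tab-separated catalog (`name`, `smarts`). Every pattern is
#' validated against OpenBabel at load time; a malformed pattern raises an
#' error naming it.
#'
#' @param which `"pains"` or `"brenk"` for the shipped subsets, or a file
#'   path to a custom catalog.
#' @return data.frame (name, smarts) with class `smarts_catalog`.
#' @export
load_alert_catalog <- function(which = c("pains", "brenk")) {
  path <- if (file.exists(which[[1L]])) {
    which[[1L]]
  } else {
    which <- match.arg(which)
    system.file("extdata", paste0(which, "_alerts_subset.tsv"),
                package = "tdpscreen", mustWork = TRUE)
  }
  cat <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smarts") %in% names(cat)))
  probe <- ob_sdfset("CCO")
  for (k in seq_len(nrow(cat))) {
    ok <- tryCatch({
      ob_smarts_count(probe, cat$smarts[k], 1L)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("Malformed SMARTS pattern '", cat$name[k], "': ",
                  cat$smarts[k], call. = FALSE)
  }
  structure(cat, class = c("smarts_catalog", "data.frame"))
}

#' Count structural-alert matches
#'
#' Number of catalog patterns with at least one substructure match in each
#' molecule, with the matched pattern names.
#'
#' @param records a `compound_set` (or character vector of standardized
#'   SMILES).
#' @param catalog a `smarts_catalog` from [load_alert_catalog()].
#' @return data.frame (id, n_alerts, alerts) where `alerts` is a
#'   `;`-separated list of matched pattern names.
#' @export
structural_alerts <- function(records, catalog) {
  smiles <- if (is.character(records)) records else records$smiles_std
  ids <- if (is.character(records)) smiles else records$id
  n <- length(smiles)
  sdfinfo <- ob_sdfset(smiles)
  hitmat <- matrix(FALSE, n, nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    cnt <- ob_smarts_count(sdfinfo, catalog$smarts[k], n)
    hitmat[, k] <- !is.na(cnt) & cnt > 0
  }
  data.frame(id = ids,
             n_alerts = rowSums(hitmat),
             alerts = vapply(seq_len(n), function(i) {
               paste(catalog$name[hitmat[i, ]], collapse = ";")
             }, character(1)),
             row.names = NULL)
}

#' Lipinski Rule-of-Five violation count
#'
#' Counts violated conditions among MW > 500, logP > 5 (OpenBabel
#' atom-contribution estimate), H-bond donors > 5 (N/O with attached
#' hydrogen) and H-bond acceptors > 10 (N + O count, the classic heuristic).
#'
#' @param x a `mol_graph`, standardized SMILES string, character vector, or
#'   `compound_set`.
#' @return integer vector of violation counts in `[0, 4]`.
#' @export
lipinski_violations <- function(x) {
  if (inherits(x, "mol_graph")) x <- write_smiles(x)
  smiles <- if (is.character(x)) x else x$smiles_std
  graphs <- lapply(smiles, parse_smiles)
  obp <- ob_properties(smiles)
  out <- integer(length(smiles))
  for (k in seq_along(graphs)) {
    at <- graphs[[k]]$atoms
    donors <- sum(at$element %in% c("N", "O") & at$n_h > 0)
    acceptors <- sum(at$element %in% c("N", "O"))
    out[k] <- sum(obp$MW[k] > 500, obp$logP[k] > 5, donors > 5,
                  acceptors > 10)
  }
  out
}

#' Maximum Tanimoto similarity to a reference set
#'
#' Novelty scoring: the maximum fingerprint similarity of each candidate to
#' the training actives (low values flag novel chemotypes).
#'
#' @param fps candidate fingerprint matrix (rows = candidates).
#' @param reference_fps fingerprint matrix of the reference (training-active)
#'   molecules; must be non-empty and of equal width.
#' @return numeric vector of maximal similarities.
#' @export
novelty <- function(fps, reference_fps) {
  fps <- as.matrix(fps); reference_fps <- as.matrix(reference_fps)
  if (nrow(reference_fps) == 0L) {
    stop("Reference fingerprint set is empty", call. = FALSE)
  }
  if (ncol(fps) != ncol(reference_fps)) {
    stop("Fingerprint length mismatch", call. = FALSE)
  }
  apply(tanimoto_matrix(fps, reference_fps), 1, max)
}

#' Virtual-screening filter cascade
#'
#' Applies, in order: predicted probability strictly above `threshold`
#' (default 0.8), zero Rule-of-Five violations, zero PAINS alerts, at most
#' one Brenk alert, blood-brain-barrier annotation true, and prior-testing
#' annotation false. Annotation-based criteria whose column is missing are
#' skipped with a prominent warning. Per-stage survivor counts are logged in
#' the `stage_log` attribute.
#'
#' @param probabilities named predicted probabilities (from
#'   [predict_library()]).
#' @param records the screening `compound_set` (ids aligned with
#'   `probabilities`).
#' @param annotations optional data.frame with `id` plus logical `bbb` and
#'   `prior_tested` columns.
#' @param threshold probability cutoff (strict `>`; default 0.8).
#' @param pains,brenk alert catalogs (defaults: the shipped subsets).
#' @param reference_fps optional training-active fingerprints for novelty
#'   scoring.
#' @return a `screen_report` data.frame: one row per compound with predicted
#'   probability, each criterion's value and pass flag, the max-Tanimoto
#'   novelty score (if references were given) and the final verdict.
#' @export
filter_cascade <- function(probabilities, records, annotations = NULL,
                           threshold = 0.8,
                           pains = load_alert_catalog("pains"),
                           brenk = load_alert_catalog("brenk"),
                           reference_fps = NULL) {
  ids <- records$id
  stopifnot(length(probabilities) == length(ids))
  out <- data.frame(id = ids, probability = unname(probabilities))
  out$pass_probability <- out$probability > threshold
  out$ro5_violations <- lipinski_violations(records)
  out$pass_ro5 <- out$ro5_violations == 0L
  pa <- structural_alerts(records, pains)
  out$pains_alerts <- pa$n_alerts
  out$pass_pains <- pa$n_alerts == 0L
  br <- structural_alerts(records, brenk)
  out$brenk_alerts <- br$n_alerts
  out$pass_brenk <- br$n_alerts <= 1L
  has_bbb <- !is.null(annotations) && "bbb" %in% names(annotations)
  has_prior <- !is.null(annotations) && "prior_tested" %in% names(annotations)
  if (has_bbb) {
    out$bbb <- annotations$bbb[match(ids, annotations$id)]
    out$pass_bbb <- !is.na(out$bbb) & out$bbb
  } else {
    warning("No 'bbb' annotation column supplied; ",
            "the blood-brain-barrier criterion is SKIPPED", call. = FALSE)
    out$pass_bbb <- TRUE
  }
  if (has_prior) {
    out$prior_tested <- annotations$prior_tested[match(ids, annotations$id)]
    out$pass_prior <- !is.na(out$prior_tested) & !out$prior_tested
  } else {
    warning("No 'prior_tested' annotation column supplied; ",
            "the prior-testing criterion is SKIPPED", call. = FALSE)
    out$pass_prior <- TRUE
  }
  if (!is.null(reference_fps)) {
    fps <- unclass(fingerprint_matrix(records, nbits = ncol(reference_fps)))
    out$max_tanimoto_to_actives <- novelty(fps, reference_fps)
  }
  stages <- c("pass_probability", "pass_ro5", "pass_pains", "pass_brenk",
              "pass_bbb", "pass_prior")
  alive <- rep(TRUE, nrow(out))
  log <- data.frame(stage = "input", survivors = nrow(out))
  for (s in stages) {
    alive <- alive & out[[s]]
    log <- rbind(log, data.frame(stage = s, survivors = sum(alive)))
  }
  out$verdict <- alive
  structure(out, class = c("screen_report", "data.frame"), stage_log = log)
}

#' Per-stage survivor counts of a screening run
#'
#' @param report a `screen_report`.
#' @return data.frame (stage, survivors).
#' @export
stage_log <- function(report) attr(report, "stage_log")
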