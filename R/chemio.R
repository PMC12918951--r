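# Molecule standardization and dataset I/O.
#
# Standardization applies, in order: explicit-hydrogen removal, metal
# disconnection, normalization rules, largest-organic-fragment selection,
# charge neutralization, and a final canonicalization pass (OpenBabel
# canonical form), which also serves as the deterministic, idempotent
# tautomer-canonicalization step. Records that fail any step are reported as
# rejects with a reason, never silently dropped.

is_metal <- function(element) element %in% METAL_ELEMENTS

# Nitro groups written uncharged (N(=O)=O) are rewritten to the
# charge-separated form [N+](=O)[O-]; the only normalization rule applied.
normalize_rules <- function(g) {
  repeat {
    hit <- FALSE
    for (a in which(g$atoms$element == "N" & g$atoms$charge == 0L)) {
      dbl_o <- which((g$bonds$i == a | g$bonds$j == a) & g$bonds$order == 2L)
      if (length(dbl_o) < 2L) next
      others <- ifelse(g$bonds$i[dbl_o] == a, g$bonds$j[dbl_o], g$bonds$i[dbl_o])
      term_o <- dbl_o[g$atoms$element[others] == "O" & g$atoms$degree[others] == 1L]
      if (length(term_o) < 2L) next
      e <- term_o[[1L]]
      o <- if (g$bonds$i[e] == a) g$bonds$j[e] else g$bonds$i[e]
      g$bonds$order[e] <- 1L
      g$atoms$charge[o] <- -1L
      g$atoms$charge[a] <- 1L
      hit <- TRUE
    }
    if (!hit) break
  }
  g
}

disconnect_metals <- function(g) {
  metal <- is_metal(g$atoms$element)
  if (!any(metal)) return(g)
  cut <- (metal[g$bonds$i] | metal[g$bonds$j]) & g$bonds$order == 1L &
    !g$bonds$aromatic
  if (any(cut)) g$bonds <- g$bonds[!cut, , drop = FALSE]
  finalize_graph(g)
}

graph_components <- function(g) {
  na <- nrow(g$atoms)
  comp <- integer(na)
  adj <- adjacency_list(na, g$bonds)
  cid <- 0L
  for (s in seq_len(na)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        w <- if (g$bonds$i[e] == v) g$bonds$j[e] else g$bonds$i[e]
        if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

subset_graph <- function(g, keep) {
  idx <- which(keep)
  remap <- integer(nrow(g$atoms))
  remap[idx] <- seq_along(idx)
  kb <- g$bonds$i %in% idx & g$bonds$j %in% idx
  bonds <- g$bonds[kb, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  rownames(bonds) <- NULL
  atoms <- g$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  new_mol_graph(atoms, bonds)
}

largest_organic_fragment <- function(g) {
  comp <- graph_components(g)
  ncomp <- max(comp)
  if (ncomp == 1L) return(g)
  mass <- MONOISOTOPIC_MASS[g$atoms$element]
  mass[is.na(mass)] <- 50
  score <- vapply(seq_len(ncomp), function(k) {
    at <- comp == k
    c(any(g$atoms$element[at] == "C"), sum(at), sum(mass[at]))
  }, numeric(3))
  # order: organic first, then heavy-atom count, then mass; ties -> first
  best <- which.max(score[1, ] * 1e9 + score[2, ] * 1e4 + score[3, ] / 1e4)
  subset_graph(g, comp == best)
}

# Neutralize protonation-state charges: anionic O/S/N gain a hydrogen,
# protonated (H-bearing) cations lose one. Quaternary nitrogens and other
# non-protonation charges are left untouched.
neutralize_charges <- function(g) {
  for (a in seq_len(nrow(g$atoms))) {
    ch <- g$atoms$charge[a]
    if (ch == -1L && g$atoms$element[a] %in% c("O", "S", "N")) {
      g$atoms$charge[a] <- 0L
      g$atoms$n_h[a] <- g$atoms$n_h[a] + 1L
    } else if (ch == 1L && g$atoms$n_h[a] > 0L &&
               g$atoms$element[a] %in% c("N", "O", "S", "P")) {
      g$atoms$charge[a] <- 0L
      g$atoms$n_h[a] <- g$atoms$n_h[a] - 1L
    }
  }
  g
}

#' Standardize SMILES strings
#'
#' Vectorized molecular standardization: explicit-hydrogen removal, metal
#' disconnection, normalization (charge-separated nitro form), largest-
#' organic-fragment selection, charge neutralization, and canonicalization
#' (OpenBabel canonical SMILES, which doubles as the deterministic tautomer-
#' canonical form). Idempotent: re-standardizing the output returns it
#' unchanged.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of standardized canonical SMILES with `NA` for
#'   rejected inputs; attribute `"reason"` holds a per-element failure reason
#'   (`NA` where standardization succeeded).
#' @export
standardize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0L) return(structure(out, reason = reason))
  can0 <- ob_canonical_noH(smiles)
  reason[is.na(can0)] <- "unparseable or valence-violating SMILES"
  todo <- which(!is.na(can0))
  mids <- character(length(todo))
  for (k in seq_along(todo)) {
    i <- todo[k]
    g <- tryCatch(parse_smiles(can0[[i]]), error = function(e) NULL)
    if (is.null(g)) { reason[i] <- "parse failure after canonicalization"; next }
    g <- disconnect_metals(g)
    g <- normalize_rules(g)
    g <- largest_organic_fragment(g)
    if (!any(g$atoms$element == "C")) {
      reason[i] <- "no organic fragment"
      next
    }
    g <- neutralize_charges(g)
    mids[k] <- write_smiles(g)
  }
  keep <- which(nzchar(mids))
  if (length(keep) > 0L) {
    final <- ob_canonical(mids[keep])
    idx <- todo[keep]
    out[idx] <- final
    reason[idx][is.na(final)] <- "canonicalization failed after standardization"
  }
  structure(out, reason = reason)
}

# Canonicalization with explicit-hydrogen deletion (first standardization step).
ob_canonical_noH <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- is.na(smiles) | !nzchar(smiles) | grepl("[ \t]", smiles)
  lines <- paste0(ifelse(bad, "", smiles), "\tm", seq_along(smiles))
  out <- ob_run(c("-ismi", "-ocan", "-d"), lines[!bad])
  res <- ob_align(out, length(smiles))
  res[bad] <- NA_character_
  res
}

#' Standardize a single SMILES string
#'
#' Scalar wrapper around [standardize_smiles()] that raises a rejected-record
#' error on failure.
#'
#' @param smiles_raw a single SMILES string.
#' @param id identifier used in the error message.
#' @return the standardized canonical SMILES string.
#' @export
standardize <- function(smiles_raw, id = smiles_raw) {
  res <- standardize_smiles(smiles_raw)
  if (is.na(res[[1L]])) {
    stop(sprintf("Record '%s' rejected: %s", id, attr(res, "reason")[[1L]]),
         call. = FALSE)
  }
  unname(res[[1L]])
}

#' Convert a standardized SMILES to a molecular graph
#'
#' @param smiles_std standardized (canonical) SMILES string.
#' @return a `mol_graph`; atom order follows the canonical SMILES atom order.
#' @export
to_graph <- function(smiles_std) parse_smiles(smiles_std)

new_compound_set <- function(df, rejects = NULL) {
  stopifnot(all(c("id", "smiles_raw", "smiles_std") %in% names(df)))
  if (is.null(df$targets)) df$targets <- replicate(nrow(df), character(0),
                                                   simplify = FALSE)
  if (is.null(df$label)) df$label <- rep(NA_integer_, nrow(df))
  structure(df, class = c("compound_set", "data.frame"),
            rejects = if (is.null(rejects))
              data.frame(id = character(0), smiles_raw = character(0),
                         reason = character(0))
            else rejects)
}

#' Rejected records of a dataset
#'
#' @param x a `compound_set` returned by [read_dataset()] or
#'   [make_compound_set()].
#' @return data.frame with columns `id`, `smiles_raw`, `reason`.
#' @export
rejects <- function(x) attr(x, "rejects")

split_target_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    unique(trimws(strsplit(s, "[;|]")[[1L]]))
  })
}

#' Build a compound set from in-memory fields
#'
#' Standardizes the molecules and collects failures into the rejects report.
#'
#' @param id character vector of unique compound identifiers.
#' @param smiles character vector of raw SMILES.
#' @param label optional binary activity labels (0/1, NA allowed).
#' @param targets optional list of character vectors of target-annotation ids
#'   (or a character vector of `;`/`|`-separated lists).
#' @return a `compound_set` data.frame (id, smiles_raw, smiles_std, label,
#'   targets list-column) with rejected rows removed and recorded in
#'   `rejects()`.
#' @export
make_compound_set <- function(id, smiles, label = NULL, targets = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("Duplicate compound ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  n <- length(id)
  stopifnot(length(smiles) == n)
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (any(!label %in% c(0L, 1L) & !is.na(label))) {
    stop("Labels must be 0, 1 or NA", call. = FALSE)
  }
  if (is.null(targets)) {
    targets <- replicate(n, character(0), simplify = FALSE)
  } else if (is.character(targets)) {
    targets <- split_target_field(targets)
  } else {
    targets <- lapply(targets, function(t) unique(as.character(t)))
  }
  std <- standardize_smiles(smiles)
  ok <- !is.na(std)
  rej <- data.frame(id = id[!ok], smiles_raw = smiles[!ok],
                    reason = attr(std, "reason")[!ok])
  df <- data.frame(id = id[ok], smiles_raw = smiles[ok],
                   smiles_std = unname(std[ok]), label = label[ok],
                   stringsAsFactors = FALSE)
  df$targets <- targets[ok]
  rownames(df) <- NULL
  new_compound_set(df, rej)
}

#' Read a compound dataset from delimited text
#'
#' Reads a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a header containing
#' columns `id` and `smiles`, and optionally `label` (0/1) and `targets`
#' (`;`- or `|`-separated identifier list). Molecules are standardized on
#' read; rows that fail standardization are collected into the rejects report
#' available via [rejects()].
#'
#' @param path file path.
#' @return a `compound_set`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("Input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE)
  miss <- setdiff(c("id", "smiles"), names(df))
  if (length(miss) > 0L) {
    stop("Missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  make_compound_set(df$id, df$smiles,
                    label = if ("label" %in% names(df)) df$label else NULL,
                    targets = if ("targets" %in% names(df))
                      as.character(df$targets) else NULL)
}

#' Read compounds from an SDF file
#'
#' Molecules are converted to SMILES via OpenBabel; the molecule title becomes
#' the compound id (falling back to `sdf_<n>` when empty).
#'
#' @param path SDF file path.
#' @param label,targets optional vectors aligned with the SDF records.
#' @return a `compound_set`.
#' @export
read_sdf_dataset <- function(path, label = NULL, targets = NULL) {
  if (!file.exists(path)) stop("Input file not found: ", path, call. = FALSE)
  assert_obabel()
  out <- suppressWarnings(system2(
    "obabel", c(shQuote(path), "-osmi", "-e"), stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(k) {
    p <- parts[[k]]
    if (length(p) >= 2L && nzchar(p[[2L]])) p[[2L]] else sprintf("sdf_%d", k)
  }, character(1))
  make_compound_set(ids, smiles, label = label, targets = targets)
}

#' Write a compound set (and its rejects) to CSV
#'
#' @param records a `compound_set`.
#' @param path output CSV path; the rejects report (if non-empty) is written
#'   next to it with suffix `_rejects.csv`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  df <- as.data.frame(records)
  df$targets <- vapply(df$targets, paste, character(1), collapse = ";")
  # the standardized structure doubles as the `smiles` column, so the output
  # is directly consumable by read_dataset()
  df <- cbind(df[, "id", drop = FALSE], smiles = df$smiles_std,
              df[, setdiff(names(df), "id"), drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  rej <- rejects(records)
  if (!is.null(rej) && nrow(rej) > 0L) {
    utils::write.csv(rej, sub("\\.csv$", "_rejects.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Remove duplicate molecules by standardized SMILES
#'
#' Keeps the first occurrence of each standardized SMILES; when `reference`
#' is given, also removes any record whose standardized SMILES occurs there
#' (e.g. screening compounds already present in the training set).
#'
#' @param records a `compound_set`.
#' @param reference optional `compound_set` of molecules to exclude.
#' @return the deduplicated `compound_set` (rejects carried through).
#' @export
deduplicate <- function(records, reference = NULL) {
  keep <- !duplicated(records$smiles_std)
  if (!is.null(reference)) {
    keep <- keep & !(records$smiles_std %in% reference$smiles_std)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_compound_set(as.data.frame(out), rejects(records))
}
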