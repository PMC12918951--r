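#' @keywords internal
"_PACKAGE"

# Thin wrappers around the OpenBabel command line. All batch conversions go
# through `obabel -e` so that one bad record never aborts a batch; records are
# keyed by synthetic titles and re-aligned afterwards, so failures surface as
# NA in input order.

ob_available <- function() nzchar(Sys.which("obabel"))

assert_obabel <- function() {
  if (!ob_available()) {
    stop("OpenBabel ('obabel') was not found on the PATH; ",
         "it is required for all molecule handling.", call. = FALSE)
  }
}

ob_run <- function(args, input_lines, drop_empty = TRUE) {
  assert_obabel()
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(input_lines, infile)
  out <- suppressWarnings(
    system2("obabel", c(shQuote(infile), args, "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  # line-oriented outputs drop blanks; block formats (SDF) keep them
  if (drop_empty) out[nzchar(out)] else out
}

# Split obabel "structure<TAB>title" output lines and re-align on titles.
ob_align <- function(out_lines, n) {
  res <- rep(NA_character_, n)
  if (length(out_lines) == 0L) return(res)
  parts <- strsplit(out_lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^m", "", p[[length(p)]])))
    if (!is.na(idx) && idx >= 1L && idx <= n) res[idx] <- p[[1L]]
  }
  res
}

#' Canonical SMILES via OpenBabel
#'
#' Converts SMILES strings to OpenBabel canonical SMILES. Unparseable or
#' valence-violating inputs yield `NA` at their position rather than an error,
#' so callers can route them to a rejects report.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- is.na(smiles) | !nzchar(smiles) | grepl("[ \t]", smiles)
  lines <- paste0(ifelse(bad, "", smiles), "\tm", seq_along(smiles))
  out <- ob_run(c("-ismi", "-ocan"), lines[!bad])
  res <- ob_align(out, length(smiles))
  res[bad] <- NA_character_
  res
}

# Bulk molecular properties from OpenBabel's descriptor plugins.
# Returns a data.frame aligned with `smiles` (NA rows for failures).
ob_properties <- function(smiles) {
  props <- c("logP", "TPSA", "MW", "MR", "HBD", "HBA1")
  n <- length(smiles)
  empty <- as.data.frame(matrix(NA_real_, n, length(props)))
  names(empty) <- props
  if (n == 0L) return(empty)
  ok <- !is.na(smiles) & nzchar(smiles)
  lines <- paste0(ifelse(ok, smiles, ""), "\tm", seq_len(n))
  out <- ob_run(c("-ismi", "-osmi", "--append", shQuote(paste(props, collapse = " "))),
                lines[ok])
  if (length(out) == 0L) return(empty)
  parts <- strsplit(out, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    fields <- strsplit(p[[2L]], " +")[[1L]]
    idx <- suppressWarnings(as.integer(sub("^m", "", fields[[1L]])))
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (!is.na(idx) && length(vals) == length(props)) empty[idx, ] <- vals
  }
  empty
}

# SDFset for ChemmineOB SMARTS matching. Molecules without bonds (single
# heavy atom) cannot be represented as a valid ChemmineR SDF; their slots
# report NA match counts.
ob_sdfset <- function(smiles) {
  n <- length(smiles)
  multi <- !is.na(smiles) & nzchar(smiles) &
    nchar(gsub("[^A-Za-z]", "", smiles)) > 1L
  idx <- which(multi)
  if (length(idx) == 0L) return(list(sdfset = NULL, index = integer(0)))
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(smiles[idx]))
  list(sdfset = sdfs, index = idx)
}

# Count of substructure matches per molecule for one SMARTS pattern.
# Molecules that could not enter the SDFset report NA.
ob_smarts_count <- function(sdfinfo, smarts, n) {
  counts <- rep(NA_real_, n)
  if (length(sdfinfo$index) == 0L) return(counts)
  hits <- tryCatch(
    ChemmineR::smartsSearchOB(sdfinfo$sdfset, smarts, uniqueMatches = TRUE),
    error = function(e) stop("SMARTS pattern failed in OpenBabel: ", smarts,
                             call. = FALSE)
  )
  counts[sdfinfo$index] <- as.numeric(hits)
  counts
}
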