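# Family-tagged feature matrices and their assembly.
#
# A feature_matrix is a numeric matrix (rows = compounds, rownames = ids)
# whose columns each belong to exactly one family: GNN, DESCRIPTOR, TARGET or
# FINGERPRINT. Descriptor columns are min-max scaled with a scaler fitted on
# training rows only; binary families are passed through unscaled.

FEATURE_FAMILIES <- c("GNN", "DESCRIPTOR", "TARGET", "FINGERPRINT")

#' Create a family-tagged feature matrix
#'
#' @param values numeric matrix with row and column names.
#' @param family a single family for all columns, or a per-column character
#'   vector (`GNN`, `DESCRIPTOR`, `TARGET` or `FINGERPRINT`).
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, family) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("Feature columns must be named",
                                      call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("Duplicate feature names",
                                            call. = FALSE)
  if (length(family) == 1L) family <- rep(family, ncol(values))
  stopifnot(length(family) == ncol(values))
  if (!all(family %in% FEATURE_FAMILIES)) {
    stop("Unknown feature family: ",
         paste(setdiff(family, FEATURE_FAMILIES), collapse = ", "),
         call. = FALSE)
  }
  structure(values, family = unname(family), class = c("feature_matrix", "matrix"))
}

#' Column families of a feature matrix
#' @param x a `feature_matrix`.
#' @return character vector, one family per column.
#' @export
feature_families <- function(x) attr(x, "family")

# Subset columns keeping the family tags in sync.
fm_select <- function(x, cols) {
  if (is.character(cols)) cols <- match(cols, colnames(x))
  feature_matrix(unclass(x)[, cols, drop = FALSE], feature_families(x)[cols])
}

fm_rows <- function(x, rows) {
  feature_matrix(unclass(x)[rows, , drop = FALSE], feature_families(x))
}

#' @export
print.feature_matrix <- function(x, ...) {
  fam <- table(feature_families(x))
  cat(sprintf("<feature_matrix> %d compounds x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
  invisible(x)
}

#' Column-wise concatenation of feature matrices
#'
#' All parts must have identical row ids in identical order; feature names
#' must not collide across parts.
#'
#' @param parts list of `feature_matrix` objects.
#' @return the combined `feature_matrix`.
#' @export
assemble_features <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  if (length(parts) == 1L) return(parts[[1L]])
  ids <- rownames(parts[[1L]])
  for (p in parts[-1L]) {
    if (!identical(rownames(p), ids)) {
      stop("Row ids differ between feature matrix parts", call. = FALSE)
    }
  }
  values <- do.call(cbind, lapply(parts, unclass))
  if (anyDuplicated(colnames(values))) {
    stop("Feature name collision: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  feature_matrix(values, unlist(lapply(parts, feature_families)))
}

#' Fit a min-max scaler on training rows
#'
#' Only `DESCRIPTOR`-family columns are scaled; binary families are passed
#' through untouched by [apply_scaler()].
#'
#' @param x a `feature_matrix`.
#' @param rows training row indices (or ids) the ranges are computed on.
#' @return a `minmax_scaler` object.
#' @export
fit_scaler <- function(x, rows = seq_len(nrow(x))) {
  fam <- feature_families(x)
  cols <- which(fam == "DESCRIPTOR")
  sub <- unclass(x)[rows, cols, drop = FALSE]
  structure(list(columns = colnames(x)[cols],
                 min = apply(sub, 2, min),
                 max = apply(sub, 2, max)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Training-range scaling to `[0, 1]`; query values outside the fitted range
#' are clipped, so held-out and screening compounds always land in `[0, 1]`.
#' Columns whose fitted range is degenerate (max == min) map to 0.
#'
#' @param scaler a `minmax_scaler` from [fit_scaler()].
#' @param x a `feature_matrix` containing the scaler's columns.
#' @return `x` with scaled descriptor columns.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vals <- unclass(x)
  cols <- scaler$columns
  if (length(cols) == 0L) return(x)
  miss <- setdiff(cols, colnames(vals))
  if (length(miss) > 0L) {
    stop("Scaler columns missing from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rng <- scaler$max - scaler$min
  for (k in seq_along(cols)) {
    v <- vals[, cols[k]]
    vals[, cols[k]] <- if (rng[k] <= 0) 0
      else pmin(1, pmax(0, (v - scaler$min[k]) / rng[k]))
  }
  feature_matrix(vals, feature_families(x))
}

#' Target-annotation vocabulary from training records
#'
#' @param records a `compound_set`.
#' @return sorted character vector of all annotation ids observed.
#' @export
build_target_vocabulary <- function(records) {
  sort(unique(unlist(records$targets)))
}

#' Binary target-annotation features
#'
#' Entry `(i, j)` is 1 iff compound `i` carries annotation `j` of the
#' vocabulary. Annotations outside the vocabulary are ignored (the vocabulary
#' is fixed on training data); compounds without annotations get all-zero
#' rows.
#'
#' @param records a `compound_set`.
#' @param vocabulary ordered character vector of annotation ids (built on
#'   training rows via [build_target_vocabulary()]).
#' @return a `feature_matrix` of family `TARGET`.
#' @export
encode_targets <- function(records, vocabulary) {
  m <- matrix(0L, nrow(records), length(vocabulary),
              dimnames = list(records$id, vocabulary))
  for (k in seq_len(nrow(records))) {
    hit <- intersect(records$targets[[k]], vocabulary)
    if (length(hit) > 0L) m[k, hit] <- 1L
  }
  feature_matrix(m, family = "TARGET")
}
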