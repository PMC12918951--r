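# Folded circular (Morgan / ECFP) fingerprints.
#
# Atom environments are identified by iterative neighborhood hashing: the
# initial identifier of an atom hashes its local invariants (atomic number,
# heavy-atom degree, formal charge, attached hydrogens, ring flag, aromatic
# flag); at each round r = 1..radius the identifier is rehashed together with
# the sorted (bond-code, neighbor-identifier) pairs. All identifiers from all
# rounds are folded modulo `nbits` into a binary vector.
#
# The hash is FNV-1a (32-bit) over the little-endian bytes of the integer
# sequence - fully specified here so that an independent implementation can
# reproduce the fingerprints bit for bit.

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30,
  Se = 34, Br = 35, I = 53
)

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619

# 32-bit FNV-1a over the 4 little-endian bytes of each integer.
fnv1a32 <- function(ints) {
  h <- FNV_OFFSET
  for (v in ints) {
    x <- v %% 4294967296
    for (b in 1:4) {
      byte <- x %% 256
      x <- (x - byte) / 256
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(byte))
      hi <- (h - h %% 65536) / 65536
      lo <- h %% 65536
      h <- ((hi * FNV_PRIME) %% 65536) * 65536 + lo * FNV_PRIME
      h <- h %% 4294967296
    }
  }
  h
}

bond_code <- function(bonds) {
  ifelse(bonds$aromatic, 4L, bonds$order)
}

# Environment identifiers for every atom and radius 0..radius.
morgan_identifiers <- function(graph, radius = 2L) {
  atoms <- graph$atoms; bonds <- graph$bonds
  na <- nrow(atoms)
  z <- ATOMIC_NUMBER[atoms$element]
  z[is.na(z)] <- 0
  ids <- numeric(na)
  for (a in seq_len(na)) {
    ids[a] <- fnv1a32(c(z[a], atoms$degree[a], atoms$charge[a] + 16L,
                        atoms$n_h[a], as.integer(atoms$in_ring[a]),
                        as.integer(atoms$aromatic[a])))
  }
  all_ids <- ids
  if (radius > 0L && nrow(bonds) > 0L) {
    bc <- bond_code(bonds)
    nbr <- vector("list", na)
    for (e in seq_len(nrow(bonds))) {
      nbr[[bonds$i[e]]] <- rbind(nbr[[bonds$i[e]]], c(bc[e], bonds$j[e]))
      nbr[[bonds$j[e]]] <- rbind(nbr[[bonds$j[e]]], c(bc[e], bonds$i[e]))
    }
    for (r in seq_len(radius)) {
      new_ids <- numeric(na)
      for (a in seq_len(na)) {
        nb <- nbr[[a]]
        if (is.null(nb)) {
          # isolated atom: the environment stops growing, keep the identifier
          new_ids[a] <- ids[a]
        } else {
          pairs <- cbind(nb[, 1L], ids[nb[, 2L]])
          ord <- order(pairs[, 1L], pairs[, 2L])
          new_ids[a] <- fnv1a32(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
        }
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  all_ids
}

#' Folded Morgan (ECFP) fingerprint
#'
#' @param graph a `mol_graph` (or standardized SMILES string).
#' @param radius neighborhood radius (default 2, i.e. ECFP4-equivalent).
#' @param nbits fingerprint length; must be a power of two (default 2048).
#' @return integer 0/1 vector of length `nbits`.
#' @export
compute_ecfp <- function(graph, radius = 2L, nbits = 2048L) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  stopifnot(inherits(graph, "mol_graph"), radius >= 0L)
  if (bitwAnd(nbits, nbits - 1L) != 0L || nbits <= 0L) {
    stop("nbits must be a power of two", call. = FALSE)
  }
  ids <- morgan_identifiers(graph, radius)
  fp <- integer(nbits)
  fp[unique(ids %% nbits) + 1L] <- 1L
  fp
}

#' Fingerprint matrix for a compound set
#'
#' @param records a `compound_set` (or character vector of standardized
#'   SMILES).
#' @param radius,nbits as in [compute_ecfp()].
#' @return a `feature_matrix` of family `FINGERPRINT` (rows = compounds).
#' @export
fingerprint_matrix <- function(records, radius = 2L, nbits = 2048L) {
  smiles <- if (is.character(records)) records else records$smiles_std
  ids <- if (is.character(records)) smiles else records$id
  m <- matrix(0L, length(smiles), nbits,
              dimnames = list(ids, sprintf("fp_%04d", seq_len(nbits) - 1L)))
  for (k in seq_along(smiles)) {
    m[k, ] <- compute_ecfp(parse_smiles(smiles[[k]]), radius, nbits)
  }
  feature_matrix(m, family = "FINGERPRINT")
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are all-zero.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("Fingerprint length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# All-pairs Tanimoto similarity between the rows of two 0/1 matrices.
tanimoto_matrix <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  inter <- tcrossprod(A, B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  s <- inter / uni
  s[uni == 0] <- 1
  s
}
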