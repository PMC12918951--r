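# Physicochemical descriptor provider.
#
# Bulk properties (MolLogP, TPSA, MW, MolMR, H-bond donors/acceptors) come
# from OpenBabel's atom-contribution models. Topological and surface-area
# descriptors are computed from the molecular graph: per-atom van der Waals
# surface areas use Labute's spherical-cap approximation over Bondi radii;
# electrotopological-state (EState) indices use the Kier-Hall intrinsic-state
# formula; the per-atom molar-refractivity contributions use a coarse
# element/aromaticity table maintained in this package. QED is Bickerton's
# weighted desirability product over MW, ALOGP, HBA, HBD, PSA, rotatable
# bonds and aromatic rings (the structural-alert term is handled separately
# by the screening module and omitted here).

BONDI_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Si = 2.10, Se = 1.90
)

COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
  S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, Si = 1.11, Se = 1.20
)

# Coarse per-atom molar-refractivity contributions (cm^3/mol); aromatic
# carbon is distinguished because ring polarisability dominates the SMR_VSA
# profile of drug-like molecules.
MR_CONTRIB <- list(
  C = c(plain = 2.50, aromatic = 3.85), N = c(plain = 2.75, aromatic = 2.90),
  O = c(plain = 1.65, aromatic = 1.80), S = c(plain = 7.90, aromatic = 7.00),
  P = c(plain = 7.40, aromatic = 7.40), F = c(plain = 1.00, aromatic = 1.00),
  Cl = c(plain = 5.90, aromatic = 5.90), Br = c(plain = 8.90, aromatic = 8.90),
  I = c(plain = 14.0, aromatic = 14.0), B = c(plain = 3.50, aromatic = 3.50)
)

ESTATE_VSA_BINS <- c(-Inf, -0.390, 0.290, 0.717, 1.165, 1.540, 1.807, 2.05,
                     4.69, 9.17, 15.0, Inf)
SMR_VSA_BINS <- c(-Inf, 1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, 3.80,
                  4.00, Inf)

PRINCIPAL_QUANTUM <- c(
  H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3, Cl = 3,
  Se = 4, Br = 4, I = 5
)

VALENCE_ELECTRONS <- c(
  H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6, Cl = 7,
  Se = 6, Br = 7, I = 7
)

# Per-atom van der Waals surface area (Labute approximation): sphere area
# minus spherical caps cut off by bonded neighbors (including hydrogens) at
# covalent bond distance.
atom_vsa <- function(graph) {
  atoms <- graph$atoms; bonds <- graph$bonds
  na <- nrow(atoms)
  ri <- BONDI_RADII[atoms$element]
  ri[is.na(ri)] <- 1.7
  area <- 4 * pi * ri^2
  cap <- function(r1, r2, d) {
    d <- min(max(d, abs(r1 - r2) + 1e-6), r1 + r2 - 1e-6)
    h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
    2 * pi * r1 * max(0, h)
  }
  rc <- COVALENT_RADII[atoms$element]
  rc[is.na(rc)] <- 0.77
  if (nrow(bonds) > 0L) {
    for (e in seq_len(nrow(bonds))) {
      a <- bonds$i[e]; b <- bonds$j[e]
      ord <- if (bonds$aromatic[e]) 1.5 else bonds$order[e]
      d <- (rc[a] + rc[b]) * (1 - 0.07 * (ord - 1))
      area[a] <- area[a] - cap(ri[a], ri[b], d)
      area[b] <- area[b] - cap(ri[b], ri[a], d)
    }
  }
  rH <- BONDI_RADII[["H"]]
  for (a in seq_len(na)) {
    nh <- atoms$n_h[a]
    if (nh > 0L) {
      d <- rc[a] + COVALENT_RADII[["H"]]
      area[a] <- area[a] - nh * cap(ri[a], rH, d)
    }
  }
  pmax(area, 0)
}

# Kier-Hall electrotopological state indices.
estate_indices <- function(graph) {
  atoms <- graph$atoms
  na <- nrow(atoms)
  L <- PRINCIPAL_QUANTUM[atoms$element]
  L[is.na(L)] <- 3
  zv <- VALENCE_ELECTRONS[atoms$element]
  zv[is.na(zv)] <- 4
  delta <- pmax(atoms$degree, 1)
  deltav <- pmax(zv - atoms$n_h, 1)
  I <- ((2 / L)^2 * deltav + 1) / delta
  D <- graph_distances(graph)
  S <- I
  for (a in seq_len(na)) {
    S[a] <- I[a] + sum((I[a] - I[-a]) / (D[a, -a] + 1)^2)
  }
  S
}

# All-pairs graph (bond-count) distances by BFS.
graph_distances <- function(graph) {
  na <- nrow(graph$atoms)
  adj <- adjacency_list(na, graph$bonds)
  D <- matrix(Inf, na, na)
  diag(D) <- 0
  for (s in seq_len(na)) {
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        w <- if (graph$bonds$i[e] == v) graph$bonds$j[e] else graph$bonds$i[e]
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

vsa_bins <- function(values, vsa, breaks, prefix) {
  bins <- cut(values, breaks, right = FALSE, labels = FALSE)
  out <- numeric(length(breaks) - 1L)
  for (k in seq_along(out)) out[k] <- sum(vsa[bins == k])
  names(out) <- paste0(prefix, seq_along(out))
  out
}

count_rotatable_bonds <- function(graph) {
  b <- graph$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- graph$atoms$degree
  triple_atom <- logical(nrow(graph$atoms))
  trip <- b$order == 3L
  triple_atom[c(b$i[trip], b$j[trip])] <- TRUE
  sum(b$order == 1L & !b$aromatic & !b$ring &
        deg[b$i] > 1L & deg[b$j] > 1L &
        !triple_atom[b$i] & !triple_atom[b$j])
}

# Number of rings (cyclomatic) in the aromatic-bond subgraph.
count_aromatic_rings <- function(graph) {
  ab <- graph$bonds[graph$bonds$aromatic, , drop = FALSE]
  if (nrow(ab) == 0L) return(0L)
  verts <- sort(unique(c(ab$i, ab$j)))
  remap <- match(seq_len(nrow(graph$atoms)), verts)
  g2 <- list(atoms = graph$atoms[verts, , drop = FALSE],
             bonds = data.frame(i = remap[ab$i], j = remap[ab$j],
                                order = ab$order, aromatic = ab$aromatic))
  comp <- graph_components(g2)
  nrow(ab) - length(verts) + max(comp)
}

exact_mol_wt <- function(graph) {
  m <- MONOISOTOPIC_MASS[graph$atoms$element]
  m[is.na(m)] <- 0
  sum(m) + sum(graph$atoms$n_h) * MONOISOTOPIC_MASS[["H"]]
}

# Bickerton desirability functions.
QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                 ROTB = 0.65, AROM = 0.48)

qed_ads <- function(x, p) {
  val <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  max(val / p[7], 1e-6)
}

qed_score <- function(props) {
  d <- vapply(names(QED_WEIGHTS), function(nm)
    qed_ads(props[[nm]], QED_ADS[[nm]]), numeric(1))
  exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
}

DESCRIPTOR_NAMES <- c(
  "MolLogP", "TPSA", "MW", "MolMR", "NumHDonors", "NumHAcceptors", "QED",
  "ExactMolWt", "HeavyAtomCount", "NumHeteroatoms", "RingCount",
  "NumAromaticRings", "NumRotatableBonds", "FractionCSP3", "NumN", "NumO",
  "NumS", "NumHalogen", "FormalCharge", "LabuteASA",
  paste0("EState_VSA", 1:11), paste0("SMR_VSA", 1:10)
)

descriptor_graph_part <- function(graph) {
  atoms <- graph$atoms
  el <- atoms$element
  vsa <- atom_vsa(graph)
  es <- estate_indices(graph)
  mr <- vapply(seq_len(nrow(atoms)), function(a) {
    tab <- MR_CONTRIB[[el[a]]]
    if (is.null(tab)) return(3)
    unname(tab[if (atoms$aromatic[a]) "aromatic" else "plain"])
  }, numeric(1))
  ncarbon <- sum(el == "C")
  sp3c <- sum(el == "C" & !atoms$aromatic &
                !(seq_len(nrow(atoms)) %in%
                    c(graph$bonds$i[graph$bonds$order >= 2L],
                      graph$bonds$j[graph$bonds$order >= 2L])))
  comp <- graph_components(graph)
  c(ExactMolWt = exact_mol_wt(graph),
    HeavyAtomCount = nrow(atoms),
    NumHeteroatoms = sum(!el %in% c("C", "H")),
    RingCount = nrow(graph$bonds) - nrow(atoms) + max(comp),
    NumAromaticRings = count_aromatic_rings(graph),
    NumRotatableBonds = count_rotatable_bonds(graph),
    FractionCSP3 = if (ncarbon > 0) sp3c / ncarbon else 0,
    NumN = sum(el == "N"), NumO = sum(el == "O"), NumS = sum(el == "S"),
    NumHalogen = sum(el %in% c("F", "Cl", "Br", "I")),
    FormalCharge = sum(atoms$charge),
    LabuteASA = sum(vsa),
    vsa_bins(es, vsa, ESTATE_VSA_BINS, "EState_VSA"),
    vsa_bins(mr, vsa, SMR_VSA_BINS, "SMR_VSA"))
}

#' Physicochemical descriptors
#'
#' Computes the package's descriptor set for one molecule or a compound set.
#' Includes OpenBabel atom-contribution properties (`MolLogP`, `TPSA`, `MW`,
#' `MolMR`, H-bond donor/acceptor counts), topological counts, Labute
#' surface-area descriptors binned by EState index (`EState_VSA*`) and by
#' molar-refractivity contribution (`SMR_VSA*`), `ExactMolWt` from
#' monoisotopic masses, and `QED`.
#'
#' @param x a `mol_graph`, a standardized SMILES string, a character vector of
#'   standardized SMILES, or a `compound_set`.
#' @return for a single molecule, a named numeric vector; otherwise a
#'   `feature_matrix` of family `DESCRIPTOR` (one row per compound).
#' @export
compute_descriptors <- function(x) {
  single <- inherits(x, "mol_graph") ||
    (is.character(x) && length(x) == 1L && !inherits(x, "compound_set"))
  if (inherits(x, "mol_graph")) {
    smiles <- write_smiles(x)
    graphs <- list(x)
    ids <- smiles
  } else if (is.character(x)) {
    smiles <- x
    graphs <- lapply(x, parse_smiles)
    ids <- x
  } else {
    smiles <- x$smiles_std
    graphs <- lapply(smiles, parse_smiles)
    ids <- x$id
  }
  obp <- ob_properties(smiles)
  if (anyNA(obp$MW)) {
    bad <- which(is.na(obp$MW))
    stop("Descriptor computation failed for: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_real_, length(graphs), length(DESCRIPTOR_NAMES),
              dimnames = list(ids, DESCRIPTOR_NAMES))
  for (k in seq_along(graphs)) {
    gp <- descriptor_graph_part(graphs[[k]])
    base <- c(MolLogP = obp$logP[k], TPSA = obp$TPSA[k], MW = obp$MW[k],
              MolMR = obp$MR[k], NumHDonors = obp$HBD[k],
              NumHAcceptors = obp$HBA1[k])
    qed <- qed_score(list(MW = base[["MW"]], ALOGP = base[["MolLogP"]],
                          HBA = base[["NumHAcceptors"]], HBD = base[["NumHDonors"]],
                          PSA = base[["TPSA"]],
                          ROTB = gp[["NumRotatableBonds"]],
                          AROM = gp[["NumAromaticRings"]]))
    m[k, ] <- c(base, QED = qed, gp)[DESCRIPTOR_NAMES]
  }
  if (single) return(m[1L, ])
  feature_matrix(m, family = "DESCRIPTOR")
}
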