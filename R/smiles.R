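# Molecular graph <-> SMILES.
#
# The reader consumes (OpenBabel-)canonical SMILES and builds the package's
# molecular-graph data model: atom order follows the SMILES atom order, so all
# downstream featurization is a pure function of the canonical string.
# Stereochemistry markers are accepted and ignored (out of scope).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# Allowed valence states (increasing); the smallest state covering the
# bond-order sum decides the implicit hydrogen count (standard SMILES reading).
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

METAL_ELEMENTS <- c(
  "Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba", "Al", "Zn",
  "Fe", "Cu", "Mn", "Co", "Ni", "Ag", "Au", "Pt", "Pd", "Hg", "Cd", "Cr",
  "Ti", "Sn", "Pb", "Bi", "Sb", "Ga", "In", "Tl", "V", "Mo", "W"
)

MONOISOTOPIC_MASS <- c(
  H = 1.007825, B = 11.009305, C = 12.0, N = 14.003074, O = 15.994915,
  F = 18.998403, P = 30.973762, S = 31.972071, Cl = 34.968853,
  Br = 78.918338, I = 126.904473, Si = 27.976927, Se = 79.916522,
  Na = 22.989770, K = 38.963707, Li = 7.016004, Ca = 39.962591,
  Mg = 23.985042, Zn = 63.929147, Fe = 55.934942, Cu = 62.929601
)

# Implicit hydrogens for a neutral organic-subset atom. Aromatic bonds count
# 1.5 towards the bond-order sum; aromatic atoms round the sum up (so a fusion
# carbon with three aromatic bonds gets none).
implicit_h_rule <- function(element, aromatic, bond_sum) {
  vals <- DEFAULT_VALENCE[[element]]
  if (is.null(vals)) return(0L)
  need <- if (aromatic) ceiling(bond_sum) else bond_sum
  fit <- vals[vals >= need]
  if (length(fit) == 0L) return(0L)
  as.integer(max(0, fit[[1L]] - need))
}

new_mol_graph <- function(atoms, bonds) {
  g <- list(atoms = atoms, bonds = bonds)
  class(g) <- "mol_graph"
  finalize_graph(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds (%d aromatic)\n",
              nrow(x$atoms), nrow(x$bonds), sum(x$bonds$aromatic)))
  invisible(x)
}

# Recompute derived attributes: degree, ring membership (bridge detection),
# conjugation flags. Ring bonds are the non-bridge edges of the heavy-atom
# graph; ring atoms are their endpoints.
finalize_graph <- function(g) {
  na <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  deg <- integer(na)
  if (nb > 0L) {
    tab <- table(factor(c(g$bonds$i, g$bonds$j), levels = seq_len(na)))
    deg <- as.integer(tab)
  }
  g$atoms$degree <- deg
  ringb <- if (nb > 0L) !bridge_edges(na, g$bonds$i, g$bonds$j) else logical(0)
  g$bonds$ring <- ringb
  inring <- logical(na)
  inring[c(g$bonds$i[ringb], g$bonds$j[ringb])] <- TRUE
  g$atoms$in_ring <- inring
  # A bond is conjugated when aromatic, or when both endpoints carry pi
  # electrons (participate in a double/triple/aromatic bond).
  if (nb > 0L) {
    pi_atom <- logical(na)
    hit <- g$bonds$aromatic | g$bonds$order >= 2L
    pi_atom[c(g$bonds$i[hit], g$bonds$j[hit])] <- TRUE
    g$bonds$conj <- g$bonds$aromatic | (pi_atom[g$bonds$i] & pi_atom[g$bonds$j])
  } else {
    g$bonds$conj <- logical(0)
  }
  g
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (e in seq_len(nrow(bonds))) {
      adj[[bonds$i[e]]] <- c(adj[[bonds$i[e]]], e)
      adj[[bonds$j[e]]] <- c(adj[[bonds$j[e]]], e)
    }
  }
  adj
}

# Tarjan bridge detection (iterative); returns logical flags over edges.
bridge_edges <- function(n, bi, bj) {
  m <- length(bi)
  adj <- vector("list", n)
  for (e in seq_len(m)) {
    adj[[bi[e]]] <- c(adj[[bi[e]]], e)
    adj[[bj[e]]] <- c(adj[[bj[e]]], e)
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack_v <- root; stack_pe <- 0L; stack_k <- 1L
    while (length(stack_v) > 0L) {
      d <- length(stack_v)
      v <- stack_v[d]
      if (stack_k[d] == 1L) { timer <- timer + 1L; disc[v] <- low[v] <- timer }
      edges <- adj[[v]]
      advanced <- FALSE
      while (stack_k[d] <= length(edges)) {
        e <- edges[[stack_k[d]]]
        stack_k[d] <- stack_k[d] + 1L
        if (e == stack_pe[d]) next
        w <- if (bi[e] == v) bj[e] else bi[e]
        if (disc[w] == 0L) {
          stack_v <- c(stack_v, w); stack_pe <- c(stack_pe, e)
          stack_k <- c(stack_k, 1L)
          advanced <- TRUE
          break
        } else {
          low[v] <- min(low[v], disc[w])
        }
      }
      if (advanced) next
      stack_v <- stack_v[-d]
      pe <- stack_pe[d]; stack_pe <- stack_pe[-d]; stack_k <- stack_k[-d]
      if (pe != 0L) {
        u <- if (bi[pe] == v) bj[pe] else bi[pe]
        low[u] <- min(low[u], low[v])
        if (low[v] > disc[u]) is_bridge[pe] <- TRUE
      }
    }
  }
  is_bridge
}

#' Parse a SMILES string into a molecular graph
#'
#' Reads a (canonical) SMILES string into the package's molecular-graph model:
#' atoms carry element, formal charge, aromatic flag, degree, ring membership
#' and attached-hydrogen count; bonds carry order plus aromatic, ring and
#' conjugation flags. Atom order follows the SMILES atom order. Stereo
#' descriptors and isotope labels are ignored.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `mol_graph`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "")[[1L]]
  n <- length(chars)
  el <- character(0); chg <- integer(0); arom <- logical(0); hexp <- integer(0)
  bi <- integer(0); bj <- integer(0); bord <- integer(0); barom <- logical(0)
  prev_stack <- integer(0)
  prev <- 0L
  pend_bond <- ""
  ring_open <- list()
  i <- 1L

  add_bond <- function(a, b, sym) {
    aromatic <- FALSE; order <- 1L
    if (sym == "=") order <- 2L
    else if (sym == "#") order <- 3L
    else if (sym == ":") aromatic <- TRUE
    else if (sym == "" && arom[a] && arom[b]) aromatic <- TRUE
    bi[length(bi) + 1L] <<- a; bj[length(bj) + 1L] <<- b
    bord[length(bord) + 1L] <<- order
    barom[length(barom) + 1L] <<- aromatic
  }
  add_atom <- function(element, aromatic, charge, hcount) {
    el[length(el) + 1L] <<- element
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    hexp[length(hexp) + 1L] <<- hcount   # -1 = implicit rule applies
    idx <- length(el)
    if (prev > 0L) add_bond(prev, idx, pend_bond)
    pend_bond <<- ""
    prev <<- idx
  }
  close_ring <- function(key) {
    if (prev == 0L) stop("Ring-closure digit before any atom in: ", smiles,
                         call. = FALSE)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- if (nzchar(pend_bond)) pend_bond else op$bond
      add_bond(op$atom, prev, sym)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pend_bond)
    }
    pend_bond <<- ""
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- if (ch %in% c("/", "\\")) "" else ch
      i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pend_bond <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      key <- paste0(chars[i + 1L], chars[i + 2L])
      close_ring(key); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("Unclosed bracket atom in SMILES: ", smiles, call. = FALSE)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]+", "", body)                  # isotope label
      m <- regmatches(body, regexec("^([A-Za-z][a-z]?)", body))[[1L]]
      sym <- m[2L]
      if (sym %in% c("se", "as")) {
        aromatic <- TRUE
      } else if (substr(sym, 1, 1) %in% c("b", "c", "n", "o", "p", "s")) {
        aromatic <- TRUE
        sym <- substr(sym, 1, 1)     # e.g. [nH] -> n, trailing char is no element
      } else {
        aromatic <- FALSE
      }
      element <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      rest <- substr(body, nchar(sym) + 1L, nchar(body))
      rest <- gsub("@+", "", rest)                      # chirality
      hcount <- 0L
      hm <- regmatches(rest, regexec("H([0-9]*)", rest))[[1L]]
      if (length(hm) > 0L) {
        hcount <- if (nzchar(hm[2L])) as.integer(hm[2L]) else 1L
        rest <- sub("H[0-9]*", "", rest)
      }
      charge <- 0L
      cm <- regmatches(rest, regexec("(\\+{1,3}|-{1,3})([0-9]*)", rest))[[1L]]
      if (length(cm) > 0L && nzchar(cm[2L])) {
        sgn <- if (substr(cm[2L], 1, 1) == "+") 1L else -1L
        mag <- if (nzchar(cm[3L])) as.integer(cm[3L]) else nchar(cm[2L])
        charge <- sgn * mag
      }
      add_atom(element, aromatic, charge, hcount)
      i <- j + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, -1L); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, -1L); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, -1L); i <- i + 1L
      } else {
        stop("Unexpected SMILES token '", ch, "' in: ", smiles, call. = FALSE)
      }
    } else {
      stop("Unexpected SMILES character '", ch, "' in: ", smiles, call. = FALSE)
    }
  }
  if (length(ring_open) > 0L && any(!vapply(ring_open, is.null, logical(1)))) {
    stop("Unmatched ring-closure in SMILES: ", smiles, call. = FALSE)
  }

  na <- length(el)
  if (na == 0L) stop("Empty SMILES string", call. = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = bord, aromatic = barom)
  n_h <- integer(na)
  bsum <- numeric(na)
  if (nrow(bonds) > 0L) {
    contrib <- ifelse(bonds$aromatic, 1.5, bonds$order)
    for (e in seq_len(nrow(bonds))) {
      bsum[bonds$i[e]] <- bsum[bonds$i[e]] + contrib[e]
      bsum[bonds$j[e]] <- bsum[bonds$j[e]] + contrib[e]
    }
  }
  for (a in seq_len(na)) {
    n_h[a] <- if (hexp[a] >= 0L) hexp[a]
      else implicit_h_rule(el[a], arom[a], bsum[a])
  }
  atoms <- data.frame(element = el, charge = chg, aromatic = arom,
                      n_h = n_h, stringsAsFactors = FALSE)
  new_mol_graph(atoms, bonds)
}

#' Write a molecular graph as a SMILES string
#'
#' Serializes a `mol_graph` back to SMILES (depth-first traversal with
#' ring-closure digits, aromatic atoms in lowercase). The output is valid input
#' for [parse_smiles()] and for OpenBabel canonicalization; it is not itself
#' canonical.
#'
#' @param graph a `mol_graph`.
#' @return a SMILES string.
#' @export
write_smiles <- function(graph) {
  atoms <- graph$atoms; bonds <- graph$bonds
  na <- nrow(atoms)
  if (na == 0L) return("")
  nb <- nrow(bonds)
  adj <- adjacency_list(na, bonds)

  # Pass 1: DFS to classify edges and assign ring-closure labels. Back edges
  # are discovered at the deeper endpoint; both endpoints get the label, the
  # deeper one also carries the bond symbol.
  visited <- logical(na)
  tree_children <- vector("list", na)     # per atom: list of (edge, child)
  marks <- vector("list", na)             # per atom: list of (label, sym)
  roots <- integer(0)
  ring_num <- 0L
  edge_state <- integer(nb)               # 0 unseen, 1 tree, 2 back

  bond_sym <- function(e, from) {
    ord <- bonds$order[e]
    if (bonds$aromatic[e]) return("")
    if (ord == 2L) return("=")
    if (ord == 3L) return("#")
    other <- if (bonds$i[e] == from) bonds$j[e] else bonds$i[e]
    if (atoms$aromatic[from] && atoms$aromatic[other]) return("-")
    ""
  }

  for (root in seq_len(na)) {
    if (visited[root]) next
    roots <- c(roots, root)
    stack <- c(root); parent_edge <- c(0L)
    visited[root] <- TRUE
    # iterative DFS preserving neighbor order
    todo <- list(list(v = root, pe = 0L))
    while (length(todo) > 0L) {
      fr <- todo[[length(todo)]]; todo[[length(todo)]] <- NULL
      v <- fr$v
      for (e in adj[[v]]) {
        if (edge_state[e] != 0L || e == fr$pe) next
        w <- if (bonds$i[e] == v) bonds$j[e] else bonds$i[e]
        if (!visited[w]) {
          edge_state[e] <- 1L
          visited[w] <- TRUE
          tree_children[[v]] <- c(tree_children[[v]], list(list(e = e, w = w)))
          todo[[length(todo) + 1L]] <- list(v = w, pe = e)
        } else {
          edge_state[e] <- 2L
          ring_num <- ring_num + 1L
          lab <- if (ring_num < 10L) as.character(ring_num)
                 else sprintf("%%%02d", ring_num)
          marks[[v]] <- c(marks[[v]], list(list(label = lab, sym = bond_sym(e, v))))
          marks[[w]] <- c(marks[[w]], list(list(label = lab, sym = "")))
        }
      }
    }
  }

  atom_token <- function(a) {
    e <- atoms$element[a]
    lower <- atoms$aromatic[a] && e %in% AROMATIC_OK
    sym <- if (lower) tolower(e) else e
    bsum <- 0
    for (ed in adj[[a]]) bsum <- bsum + if (bonds$aromatic[ed]) 1.5 else bonds$order[ed]
    plain_ok <- e %in% ORGANIC_SUBSET && atoms$charge[a] == 0L &&
      (!atoms$aromatic[a] || lower) &&
      implicit_h_rule(e, atoms$aromatic[a], bsum) == atoms$n_h[a]
    if (plain_ok) return(sym)
    h <- atoms$n_h[a]
    hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- atoms$charge[a]
    cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
      else sprintf("%+d", ch)
    paste0("[", sym, hpart, cpart, "]")
  }

  # Pass 2: emit. Recursive over the explicit tree (molecules are small).
  emit <- function(v, incoming_sym) {
    parts <- paste0(incoming_sym, atom_token(v))
    for (mk in marks[[v]]) parts <- paste0(parts, mk$sym, mk$label)
    kids <- tree_children[[v]]
    nk <- length(kids)
    if (nk > 0L) {
      for (k in seq_len(nk)) {
        sub <- emit(kids[[k]]$w, bond_sym(kids[[k]]$e, v))
        parts <- if (k < nk) paste0(parts, "(", sub, ")")
                 else paste0(parts, sub)
      }
    }
    parts
  }
  paste0(vapply(roots, function(r) emit(r, ""), character(1)), collapse = ".")
}
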