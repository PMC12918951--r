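# Post-hoc interpretability: exact tree-conditional Shapley attributions for
# the boosted ensemble, correlation between target annotations and
# descriptors, Monte-Carlo-tree-search subgraph rationales from the embedding
# network, and a t-SNE chemical-space map.

#' Shapley attributions for a boosted ensemble
#'
#' Exact tree-conditional Shapley values via the polynomial tree-traversal
#' (TreeSHAP) recursion, computed in double precision so that local accuracy
#' holds to 1e-6: the base value plus the per-feature attributions equals the
#' model margin for every row.
#'
#' @param model a `booster_model`.
#' @param x a `feature_matrix` with the model's training columns.
#' @return an `attribution` object: list with `values` (rows x features),
#'   `base` (expected margin) and `feature_values`.
#' @export
shapley_attributions <- function(model, x) {
  vals <- unclass(x)
  if (!all(model$features %in% colnames(vals))) {
    stop("Feature columns do not match the fitted model", call. = FALSE)
  }
  vals <- vals[, model$features, drop = FALSE]
  ts <- treeshap_values(model, vals)
  structure(list(values = ts$values,
                 base = ts$base,
                 feature_values = vals,
                 families = feature_families(x)[match(model$features,
                                                      colnames(x))]),
            class = "attribution")
}

#' Rank features by mean absolute Shapley value
#'
#' @param attributions an `attribution` from [shapley_attributions()].
#' @param top_k number of features to return (default 30; capped at the
#'   feature count).
#' @return data.frame (feature, family, mean_abs_shap) in decreasing order,
#'   with a `beeswarm` attribute holding the long-format per-row table
#'   (feature, row, shap, value).
#' @export
rank_features <- function(attributions, top_k = 30L) {
  mabs <- colMeans(abs(attributions$values))
  ord <- order(-mabs, seq_along(mabs))
  ord <- ord[seq_len(min(top_k, length(ord)))]
  out <- data.frame(feature = colnames(attributions$values)[ord],
                    family = attributions$families[ord],
                    mean_abs_shap = mabs[ord], row.names = NULL)
  long <- do.call(rbind, lapply(ord, function(j) {
    data.frame(feature = colnames(attributions$values)[j],
               row = rownames(attributions$feature_values) %||%
                 as.character(seq_len(nrow(attributions$values))),
               shap = attributions$values[, j],
               value = attributions$feature_values[, j], row.names = NULL)
  }))
  attr(out, "beeswarm") <- long
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation between target annotations and descriptors
#'
#' Pearson correlation for every (TARGET, DESCRIPTOR) pair of the supplied
#' columns; pairs involving a constant column report r = 0 and are flagged.
#'
#' @param x a `feature_matrix` containing both families.
#' @param targets,descriptors optional column subsets (default: all columns
#'   of the respective family).
#' @return data.frame (target, descriptor, r, constant).
#' @export
target_descriptor_correlation <- function(x, targets = NULL,
                                          descriptors = NULL) {
  fam <- feature_families(x)
  if (is.null(targets)) targets <- colnames(x)[fam == "TARGET"]
  if (is.null(descriptors)) descriptors <- colnames(x)[fam == "DESCRIPTOR"]
  if (length(targets) == 0L || length(descriptors) == 0L) {
    stop("Need both TARGET and DESCRIPTOR columns", call. = FALSE)
  }
  vals <- unclass(x)
  out <- expand.grid(target = targets, descriptor = descriptors,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$constant <- FALSE
  for (k in seq_len(nrow(out))) {
    a <- vals[, out$target[k]]; b <- vals[, out$descriptor[k]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$r[k] <- 0; out$constant[k] <- TRUE
    } else {
      out$r[k] <- stats::cor(a, b)
    }
  }
  out
}

# ---- subgraph handling for rationales -------------------------------------

# Induced subgraph with hydrogen patching: broken aromatic systems are
# demoted to single bonds (a bond stays aromatic only if it lies on a cycle
# of aromatic bonds), and implicit hydrogen counts are recomputed so every
# fragment is a valid molecule.
induced_subgraph_patched <- function(graph, keep_atoms) {
  keep <- logical(nrow(graph$atoms))
  keep[keep_atoms] <- TRUE
  g <- subset_graph(graph, keep)
  nb <- nrow(g$bonds)
  if (nb > 0L) {
    ar <- which(g$bonds$aromatic)
    if (length(ar) > 0L) {
      verts <- sort(unique(c(g$bonds$i[ar], g$bonds$j[ar])))
      remap <- match(g$bonds$i[ar], verts)
      remap2 <- match(g$bonds$j[ar], verts)
      br <- bridge_edges(length(verts), remap, remap2)
      demote <- ar[br]
      if (length(demote) > 0L) {
        g$bonds$aromatic[demote] <- FALSE
        g$bonds$order[demote] <- 1L
      }
    }
    arom_atom <- logical(nrow(g$atoms))
    stillar <- which(g$bonds$aromatic)
    arom_atom[c(g$bonds$i[stillar], g$bonds$j[stillar])] <- TRUE
    g$atoms$aromatic <- arom_atom
  } else {
    g$atoms$aromatic <- FALSE
  }
  # re-derive implicit hydrogens for neutral atoms
  bsum <- numeric(nrow(g$atoms))
  if (nb > 0L) {
    contrib <- ifelse(g$bonds$aromatic, 1.5, g$bonds$order)
    for (e in seq_len(nb)) {
      bsum[g$bonds$i[e]] <- bsum[g$bonds$i[e]] + contrib[e]
      bsum[g$bonds$j[e]] <- bsum[g$bonds$j[e]] + contrib[e]
    }
  }
  for (a in seq_len(nrow(g$atoms))) {
    if (g$atoms$charge[a] == 0L &&
        !is.null(DEFAULT_VALENCE[[g$atoms$element[a]]])) {
      g$atoms$n_h[a] <- implicit_h_rule(g$atoms$element[a],
                                        g$atoms$aromatic[a], bsum[a])
    }
  }
  finalize_graph(g)
}

# Candidate deletions from the current atom subset: single non-ring atoms
# whose removal keeps the fragment connected, and whole pendant ring systems.
rationale_actions <- function(graph, atoms) {
  g <- induced_subgraph_patched(graph, atoms)
  n <- length(atoms)
  acts <- list()
  connected_after <- function(drop_local) {
    rest <- setdiff(seq_len(n), drop_local)
    if (length(rest) == 0L) return(FALSE)
    sub <- subset_graph(g, seq_len(n) %in% rest)
    max(graph_components(sub)) == 1L
  }
  for (a in which(!g$atoms$in_ring)) {
    if (connected_after(a)) acts[[length(acts) + 1L]] <- atoms[a]
  }
  ring_atoms <- which(g$atoms$in_ring)
  if (length(ring_atoms) > 0L) {
    sub <- subset_graph(g, seq_len(n) %in% ring_atoms)
    comp <- graph_components(sub)
    for (k in seq_len(max(comp))) {
      sys <- ring_atoms[comp == k]
      if (length(sys) < n && connected_after(sys)) {
        acts[[length(acts) + 1L]] <- atoms[sys]
      }
    }
  }
  acts
}

#' Monte-Carlo-tree-search subgraph rationales
#'
#' Searches connected subgraphs of a molecule for substructures that the
#' trained embedding network scores as active. The root is the whole
#' molecule; actions delete a peripheral (non-ring, non-cut) atom or a whole
#' pendant ring system; the reward of a state is the network's predicted
#' activity probability for the hydrogen-patched fragment. Selection uses
#' UCT with exploration constant `c_explore`.
#'
#' @param model a trained `mpnn_model` (encoder + classification head).
#' @param graph a `mol_graph` (or standardized SMILES).
#' @param min_atoms,max_atoms size window for reported rationales (defaults
#'   8 and 20).
#' @param n_rollouts number of UCT rollouts (default 500).
#' @param c_explore exploration constant (default 10).
#' @param seed integer seed (tie-breaking among equal UCT scores).
#' @param top_k number of rationales to return.
#' @return data.frame (smiles, n_atoms, score, visits, atoms list-column),
#'   best first; zero rows when the molecule is smaller than `min_atoms` or
#'   `n_rollouts` is 0.
#' @export
mcts_rationale <- function(model, graph, min_atoms = 8L, max_atoms = 20L,
                           n_rollouts = 500L, c_explore = 10,
                           seed = 1L, top_k = 5L) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  n0 <- nrow(graph$atoms)
  empty <- data.frame(smiles = character(0), n_atoms = integer(0),
                      score = numeric(0), visits = integer(0))
  if (n0 < min_atoms) {
    warning("Molecule smaller than min_atoms; no rationale extracted",
            call. = FALSE)
    return(empty)
  }
  if (n_rollouts <= 0L) return(empty)

  score_cache <- new.env(parent = emptyenv())
  state_score <- function(atoms) {
    key <- paste(atoms, collapse = ",")
    if (!is.null(score_cache[[key]])) return(score_cache[[key]])
    g <- induced_subgraph_patched(graph, atoms)
    s <- predict_mpnn(model, list(g))
    score_cache[[key]] <- s
    s
  }
  nodes <- new.env(parent = emptyenv())
  node_key <- function(atoms) paste(atoms, collapse = ",")
  get_node <- function(atoms) {
    key <- node_key(atoms)
    nd <- nodes[[key]]
    if (is.null(nd)) {
      acts <- if (length(atoms) > min_atoms) rationale_actions(graph, atoms)
              else list()
      nd <- list(atoms = atoms, W = 0, N = 0L, actions = acts,
                 children = vector("list", length(acts)))
      nodes[[key]] <- nd
    }
    nd
  }
  rng <- local_rng(seed)
  root_atoms <- seq_len(n0)
  get_node(root_atoms)
  for (r in seq_len(n_rollouts)) {
    path <- list(root_atoms)
    atoms <- root_atoms
    repeat {
      nd <- get_node(atoms)
      if (length(nd$actions) == 0L) break
      kid_N <- vapply(seq_along(nd$actions), function(k) {
        ck <- nd$children[[k]]
        if (is.null(ck)) 0L else nodes[[ck]]$N
      }, integer(1))
      if (any(kid_N == 0L)) {
        unexp <- which(kid_N == 0L)
        pick <- unexp[sample_local(rng, length(unexp), 1L)]
        child_atoms <- setdiff(atoms, nd$actions[[pick]])
        ck <- node_key(child_atoms)
        get_node(child_atoms)
        nd$children[[pick]] <- ck
        nodes[[node_key(atoms)]] <- nd
        path[[length(path) + 1L]] <- child_atoms
        atoms <- child_atoms
        break
      }
      ucb <- vapply(seq_along(nd$actions), function(k) {
        ch <- nodes[[nd$children[[k]]]]
        ch$W / ch$N + c_explore * sqrt(log(nd$N + 1) / ch$N)
      }, numeric(1))
      pick <- which.max(ucb)
      path[[length(path) + 1L]] <- child_atoms <- setdiff(atoms, nd$actions[[pick]])
      atoms <- child_atoms
    }
    reward <- state_score(atoms)
    for (st in path) {
      key <- node_key(st)
      nd <- nodes[[key]]
      nd$W <- nd$W + reward
      nd$N <- nd$N + 1L
      nodes[[key]] <- nd
    }
  }
  keys <- ls(nodes)
  rows <- list()
  for (key in keys) {
    nd <- nodes[[key]]
    sz <- length(nd$atoms)
    if (sz < min_atoms || sz > max_atoms) next
    rows[[length(rows) + 1L]] <- data.frame(
      key = key, n_atoms = sz, score = state_score(nd$atoms),
      visits = nd$N, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, tab$n_atoms), , drop = FALSE]
  tab <- utils::head(tab, top_k)
  atom_sets <- lapply(strsplit(tab$key, ","), as.integer)
  smiles <- vapply(atom_sets, function(at) {
    smi <- write_smiles(induced_subgraph_patched(graph, at))
    can <- ob_canonical(smi)
    if (is.na(can)) smi else can
  }, character(1))
  out <- data.frame(smiles = smiles, n_atoms = tab$n_atoms,
                    score = tab$score, visits = tab$visits,
                    row.names = NULL)
  out$atoms <- atom_sets
  out
}

# ---- t-SNE chemical-space map ---------------------------------------------

# Per-row conditional affinities at the requested perplexity (binary search
# over the Gaussian bandwidth).
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < 1e-12) sumP <- 1e-12
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P
}

#' t-SNE chemical-space map
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbour embedding of
#' fingerprint vectors with PCA initialization, early exaggeration and
#' momentum gradient descent.
#'
#' @param fps 0/1 fingerprint matrix (rows = compounds) or `feature_matrix`.
#' @param perplexity Gaussian perplexity (default 50; reduced with a warning
#'   when fewer than `3 * perplexity + 1` rows are supplied).
#' @param max_iter gradient-descent iterations (default 1200).
#' @param learning_rate gradient step size (default 200).
#' @param init `"pca"` (default) or `"random"`.
#' @param seed integer seed.
#' @param class optional per-row tag copied into the output.
#' @return data.frame (id, x, y, class).
#' @export
chemical_space_map <- function(fps, perplexity = 50, max_iter = 1200,
                               learning_rate = 200, init = "pca", seed = 1L,
                               class = NULL) {
  X <- as.matrix(fps)
  n <- nrow(X)
  if (n < 3 * perplexity + 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("Perplexity reduced to ", perplexity, " for ", n, " rows",
            call. = FALSE)
  }
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_preserved_seed(seed, {
    Y <- if (identical(init, "pca")) {
      pc <- stats::prcomp(X, rank. = 2L)
      pc$x[, 1:2] * 1e-4 / max(abs(pc$x[, 1:2]))
    } else {
      matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    }
    vel <- Y * 0
    gains <- Y * 0 + 1
    exa <- 12
    for (it in seq_len(max_iter)) {
      mult <- if (it <= 250) exa else 1
      mom <- if (it <= 250) 0.5 else 0.8
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (mult * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      gains <- pmax(ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8),
                    0.01)
      vel <- mom * vel - learning_rate * (gains * grad)
      Y <- Y + vel
      Y <- sweep(Y, 2, colMeans(Y))
    }
    out <- data.frame(id = rownames(X) %||% as.character(seq_len(n)),
                      x = Y[, 1], y = Y[, 2])
    out$class <- if (is.null(class)) NA_character_ else as.character(class)
    out
  })
}
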