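# Directed message-passing neural network (D-MPNN) for binary activity
# classification, used downstream as a molecular embedding extractor.
#
# Every covalent bond is represented as two directed edges. Edge hidden
# states are initialized from the source-atom and bond features, then updated
# T-1 times by summing the hidden states of edges flowing into the source
# atom, excluding the reverse edge:
#
#   h0(v->w)    = relu(W_in [x_v ; e_vw])
#   m_t(v->w)   = sum_{k in N(v) \ {w}} h_t(k->v)
#   h_{t+1}     = relu(h0 + W_msg m_t)
#
# After message passing, edge states entering each atom are aggregated into
# atom embeddings, and the molecule embedding is their mean:
#
#   a_v = relu(W_atom [x_v ; sum_k h(k->v)]),   z = mean_v a_v
#
# A feedforward head on z produces the activity logit. Gradients are derived
# by hand; optimization is Adam with weighted binary cross-entropy, early
# stopping on validation loss, and restoration of the best checkpoint.

MPNN_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

atom_feature_dim <- function() length(MPNN_ELEMENTS) + 1L + 6L + 1L + 1L + 5L + 1L
bond_feature_dim <- function() 6L

atom_features <- function(atoms) {
  n <- nrow(atoms)
  el <- matrix(0, n, length(MPNN_ELEMENTS) + 1L)
  idx <- match(atoms$element, MPNN_ELEMENTS)
  idx[is.na(idx)] <- length(MPNN_ELEMENTS) + 1L
  el[cbind(seq_len(n), idx)] <- 1
  deg <- matrix(0, n, 6L)
  deg[cbind(seq_len(n), pmin(atoms$degree, 5L) + 1L)] <- 1
  hh <- matrix(0, n, 5L)
  hh[cbind(seq_len(n), pmin(atoms$n_h, 4L) + 1L)] <- 1
  cbind(el, deg, atoms$charge, as.numeric(atoms$aromatic), hh,
        as.numeric(atoms$in_ring))
}

bond_features <- function(bonds) {
  n <- nrow(bonds)
  ord <- matrix(0, n, 4L)
  code <- ifelse(bonds$aromatic, 4L, pmin(bonds$order, 3L))
  if (n > 0L) ord[cbind(seq_len(n), code)] <- 1
  cbind(ord, as.numeric(bonds$conj), as.numeric(bonds$ring))
}

#' Directed-edge structure of a molecular graph
#'
#' Expands each bond into two directed edges and records, for every directed
#' edge v->w, the reverse-edge index used for the exclusion rule.
#'
#' @param graph a `mol_graph`.
#' @return list with `src`, `dst`, `rev` (integer vectors over directed
#'   edges), `xa` (atom feature matrix) and `xe` (edge input features
#'   `[x_src ; e_bond]`).
#' @export
build_directed_graph <- function(graph) {
  nb <- nrow(graph$bonds)
  xa <- atom_features(graph$atoms)
  if (nb == 0L) {
    return(list(src = integer(0), dst = integer(0), rev = integer(0),
                xa = xa, xe = matrix(0, 0, ncol(xa) + bond_feature_dim()),
                n_atoms = nrow(graph$atoms)))
  }
  xb <- bond_features(graph$bonds)
  src <- c(graph$bonds$i, graph$bonds$j)
  dst <- c(graph$bonds$j, graph$bonds$i)
  rev <- c(seq_len(nb) + nb, seq_len(nb))
  xe <- cbind(xa[src, , drop = FALSE], rbind(xb, xb))
  list(src = src, dst = dst, rev = rev, xa = xa, xe = xe,
       n_atoms = nrow(graph$atoms))
}

# Combine per-molecule directed structures into one batch with index offsets
# and sparse gather/scatter operators.
batch_structures <- function(structs) {
  n_mol <- length(structs)
  n_atoms <- vapply(structs, `[[`, numeric(1), "n_atoms")
  n_edges <- vapply(structs, function(s) length(s$src), numeric(1))
  aoff <- cumsum(c(0, n_atoms[-n_mol]))
  eoff <- cumsum(c(0, n_edges[-n_mol]))
  src <- unlist(lapply(seq_len(n_mol), function(k) structs[[k]]$src + aoff[k]))
  dst <- unlist(lapply(seq_len(n_mol), function(k) structs[[k]]$dst + aoff[k]))
  rev <- unlist(lapply(seq_len(n_mol), function(k) structs[[k]]$rev + eoff[k]))
  xa <- do.call(rbind, lapply(structs, `[[`, "xa"))
  xe <- do.call(rbind, lapply(structs, `[[`, "xe"))
  V <- sum(n_atoms); E <- sum(n_edges)
  A_in <- Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1, dims = c(V, E))
  P <- Matrix::sparseMatrix(
    i = rep(seq_len(n_mol), n_atoms),
    j = seq_len(V),
    x = rep(1 / n_atoms, n_atoms), dims = c(n_mol, V))
  list(src = src, dst = dst, rev = rev, xa = xa, xe = xe,
       A_in = A_in, P = P, n_mol = n_mol)
}

#' D-MPNN configuration
#'
#' The `desk` profile is a scaled-down network for laptop-scale data
#' (depth 2, hidden 64); `paper` mirrors a production-scale configuration
#' (depth 3, hidden 1300, 3 feedforward layers of 1500, dropout 0.3).
#'
#' @param depth number of edge hidden states (message passes = depth - 1).
#' @param hidden message hidden dimension (also the embedding length).
#' @param ffn_hidden,ffn_layers feedforward head width and depth.
#' @param dropout dropout rate in the feedforward head.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param max_epochs,patience early-stopping schedule.
#' @param pos_weight positive-class weight; `NULL` = N_inactive/N_active of
#'   the training partition.
#' @param seed integer seed controlling initialization and batching.
#' @param profile `"desk"` or `"paper"` presets (overridden by explicit
#'   arguments).
#' @return an `mpnn_config` list.
#' @export
mpnn_config <- function(depth = NULL, hidden = NULL, ffn_hidden = NULL,
                        ffn_layers = NULL, dropout = NULL, batch_size = NULL,
                        lr = NULL, max_epochs = NULL, patience = 5L,
                        pos_weight = NULL, seed = 1L,
                        profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(depth = 2L, hidden = 64L, ffn_hidden = 64L, ffn_layers = 1L,
         dropout = 0.1, batch_size = 32L, lr = 3e-3, max_epochs = 10L)
  } else {
    list(depth = 3L, hidden = 1300L, ffn_hidden = 1500L, ffn_layers = 3L,
         dropout = 0.3, batch_size = 64L, lr = 1e-4, max_epochs = 30L)
  }
  override <- list(depth = depth, hidden = hidden, ffn_hidden = ffn_hidden,
                   ffn_layers = ffn_layers, dropout = dropout,
                   batch_size = batch_size, lr = lr, max_epochs = max_epochs)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  }
  base$patience <- patience
  base$pos_weight <- pos_weight
  base$seed <- as.integer(seed)
  base$profile <- profile
  structure(base, class = "mpnn_config")
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

mpnn_init <- function(config) {
  da <- atom_feature_dim()
  de <- da + bond_feature_dim()
  h <- config$hidden
  w <- list(W_in = glorot(de, h), W_msg = glorot(h, h),
            W_atom = glorot(da + h, h))
  prev <- h
  for (l in seq_len(config$ffn_layers)) {
    w[[paste0("F", l)]] <- glorot(prev, config$ffn_hidden)
    w[[paste0("Fb", l)]] <- numeric(config$ffn_hidden)
    prev <- config$ffn_hidden
  }
  w$W_out <- glorot(prev, 1L)
  w$b_out <- 0
  w
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass to molecule embeddings and logits. `drop_masks` (training
# only) is a list of precomputed dropout masks per FFN layer.
mpnn_forward <- function(w, bat, config, drop_masks = NULL, keep_cache = FALSE) {
  Tdepth <- config$depth
  U0 <- bat$xe %*% w$W_in
  H <- relu(U0)
  cache <- list(U0 = U0, H = list(H), M = list())
  if (nrow(U0) > 0L) {
    for (t in seq_len(Tdepth - 1L)) {
      inc <- as.matrix(bat$A_in %*% H)
      M <- inc[bat$src, , drop = FALSE] - H[bat$rev, , drop = FALSE]
      U <- U0 + M %*% w$W_msg
      H <- relu(U)
      cache$M[[t]] <- M
      cache$H[[t + 1L]] <- H
    }
  }
  inc_f <- as.matrix(bat$A_in %*% H)
  Xcat <- cbind(bat$xa, inc_f)
  Ua <- Xcat %*% w$W_atom
  Ha <- relu(Ua)
  Z <- as.matrix(bat$P %*% Ha)
  cache$Xcat <- Xcat; cache$Ua <- Ua; cache$Z <- Z
  # feedforward head
  f <- Z
  cache$F <- list()
  for (l in seq_len(config$ffn_layers)) {
    u <- sweep(f %*% w[[paste0("F", l)]], 2, -w[[paste0("Fb", l)]])
    f <- relu(u)
    if (!is.null(drop_masks)) f <- f * drop_masks[[l]]
    cache$F[[l]] <- list(u = u, f = f)
  }
  logit <- drop(f %*% w$W_out + w$b_out)
  cache$f_last <- f
  if (keep_cache) list(logit = logit, Z = Z, cache = cache)
  else list(logit = logit, Z = Z)
}

mpnn_backward <- function(w, bat, config, cache, dlogit) {
  g <- list()
  f_last <- cache$f_last
  g$W_out <- crossprod(f_last, dlogit)
  g$b_out <- sum(dlogit)
  df <- dlogit %*% t(w$W_out)
  for (l in rev(seq_len(config$ffn_layers))) {
    lc <- cache$F[[l]]
    du <- df * (lc$u > 0)
    inp <- if (l == 1L) cache$Z else cache$F[[l - 1L]]$f
    g[[paste0("F", l)]] <- crossprod(inp, du)
    g[[paste0("Fb", l)]] <- colSums(du)
    df <- du %*% t(w[[paste0("F", l)]])
  }
  dZ <- df
  dHa <- as.matrix(Matrix::crossprod(bat$P, dZ))
  dUa <- dHa * (cache$Ua > 0)
  g$W_atom <- crossprod(cache$Xcat, dUa)
  dXcat <- dUa %*% t(w$W_atom)
  dinc <- dXcat[, ncol(bat$xa) + seq_len(config$hidden), drop = FALSE]
  dH <- as.matrix(Matrix::crossprod(bat$A_in, dinc))
  dU0 <- matrix(0, nrow(cache$U0), ncol(cache$U0))
  g$W_msg <- matrix(0, config$hidden, config$hidden)
  if (nrow(cache$U0) > 0L) {
    for (t in rev(seq_len(config$depth - 1L))) {
      U <- cache$U0 + cache$M[[t]] %*% w$W_msg
      dU <- dH * (U > 0)
      dU0 <- dU0 + dU
      g$W_msg <- g$W_msg + crossprod(cache$M[[t]], dU)
      dM <- dU %*% t(w$W_msg)
      dinc2 <- rowsum(dM, bat$src, reorder = FALSE)
      dincV <- matrix(0, nrow(bat$xa), config$hidden)
      dincV[as.integer(rownames(dinc2)), ] <- dinc2
      dH <- as.matrix(Matrix::crossprod(bat$A_in, dincV)) -
        dM[bat$rev, , drop = FALSE]
    }
    dU0 <- dU0 + dH * (cache$U0 > 0)
  }
  g$W_in <- crossprod(bat$xe, dU0)
  g
}

adam_state <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

weighted_bce <- function(logit, y, pos_weight) {
  p <- 1 / (1 + exp(-logit))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  wts <- ifelse(y == 1, pos_weight, 1)
  -sum(wts * (y * log(p) + (1 - y) * log(1 - p))) / sum(wts)
}

#' Train the D-MPNN encoder and classification head
#'
#' Minimizes class-weighted binary cross-entropy with Adam; stops early when
#' the validation loss has not improved for `patience` epochs (at most
#' `max_epochs`), restoring the best-validation weights. Fully deterministic
#' given `config$seed`.
#'
#' @param graphs list of `mol_graph` objects.
#' @param labels binary labels aligned with `graphs`.
#' @param train_idx,val_idx index vectors into `graphs` for the training and
#'   validation partitions (both must contain both classes).
#' @param config an [mpnn_config()].
#' @return an `mpnn_model`: list with `weights`, `config`, `history`
#'   (per-epoch train/validation loss) and `best_epoch`.
#' @export
train_mpnn <- function(graphs, labels, train_idx, val_idx, config = mpnn_config()) {
  stopifnot(inherits(config, "mpnn_config"))
  y_tr <- labels[train_idx]
  if (length(unique(y_tr)) < 2L || length(unique(labels[val_idx])) < 2L) {
    stop("Training and validation partitions must both contain both classes",
         call. = FALSE)
  }
  pos_weight <- config$pos_weight
  if (is.null(pos_weight)) pos_weight <- sum(y_tr == 0) / sum(y_tr == 1)
  structs <- lapply(graphs, build_directed_graph)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  w <- mpnn_init(config)
  st <- adam_state(w)
  ord <- sample(train_idx)
  nb <- ceiling(length(ord) / config$batch_size)
  batches <- split(ord, rep(seq_len(nb), each = config$batch_size,
                            length.out = length(ord)))
  bats <- lapply(batches, function(ix) batch_structures(structs[ix]))
  val_bat <- batch_structures(structs[val_idx])
  y_val <- labels[val_idx]
  best <- list(loss = Inf, w = w, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    tr_loss <- 0; tr_wsum <- 0
    for (b in seq_along(bats)) {
      bat <- bats[[b]]
      yb <- labels[batches[[b]]]
      masks <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        masks <- lapply(seq_len(config$ffn_layers), function(l)
          matrix(stats::rbinom(bat$n_mol * config$ffn_hidden, 1L, keep) / keep,
                 bat$n_mol, config$ffn_hidden))
      }
      fw <- mpnn_forward(w, bat, config, drop_masks = masks, keep_cache = TRUE)
      p <- 1 / (1 + exp(-fw$logit))
      wts <- ifelse(yb == 1, pos_weight, 1)
      dlogit <- matrix(wts * (p - yb) / sum(wts), ncol = 1L)
      g <- mpnn_backward(w, bat, config, fw$cache, dlogit)
      upd <- adam_step(w, g, st, config$lr)
      w <- upd$w; st <- upd$st
      tr_loss <- tr_loss + weighted_bce(fw$logit, yb, pos_weight) * sum(wts)
      tr_wsum <- tr_wsum + sum(wts)
    }
    val_fw <- mpnn_forward(w, val_bat, config)
    val_loss <- weighted_bce(val_fw$logit, y_val, pos_weight)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss / tr_wsum,
                                         val_loss = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, w = w, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(weights = best$w, config = config, history = history,
                 best_epoch = best$epoch, pos_weight = pos_weight),
            class = "mpnn_model")
}

#' @export
print.mpnn_model <- function(x, ...) {
  cat(sprintf("<mpnn_model> depth %d, hidden %d; best epoch %d (val loss %.4f)\n",
              x$config$depth, x$config$hidden, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Random-search hyperparameter tuning for the D-MPNN
#'
#' Draws `n_trials` seeded configurations from the search ranges (depth 2-6,
#' hidden and feedforward dimensions 300-2400, feedforward layers 1-3,
#' dropout 0.1-0.6, batch size 32 or 64), trains each and returns the
#' configuration with the lowest validation loss. `scale` shrinks the
#' dimension ranges for desk-scale runs.
#'
#' @param graphs,labels,train_idx,val_idx as in [train_mpnn()].
#' @param n_trials number of sampled configurations (default 15).
#' @param seed integer seed.
#' @param scale multiplier applied to hidden-dimension ranges (default 1).
#' @param max_epochs epochs per trial.
#' @return list with `config` (best `mpnn_config`), `trials` data.frame.
#' @export
tune_mpnn <- function(graphs, labels, train_idx, val_idx, n_trials = 15L,
                      seed = 1L, scale = 1, max_epochs = 10L) {
  rng <- local_rng(seed)
  draws <- sample_local(rng, 1e6, size = 6L * n_trials)
  trials <- data.frame()
  best <- NULL
  for (k in seq_len(n_trials)) {
    u <- draws[(k - 1L) * 6L + 1:6] / 1e6
    cfg <- mpnn_config(
      depth = 2L + floor(u[1] * 5) %% 5L,
      hidden = max(8L, as.integer(round((300 + u[2] * 2100) * scale))),
      ffn_hidden = max(8L, as.integer(round((300 + u[3] * 2100) * scale))),
      ffn_layers = 1L + floor(u[4] * 3) %% 3L,
      dropout = 0.1 + u[5] * 0.5,
      batch_size = if (u[6] < 0.5) 32L else 64L,
      max_epochs = max_epochs, seed = seed)
    fit <- train_mpnn(graphs, labels, train_idx, val_idx, cfg)
    vloss <- min(fit$history$val_loss)
    trials <- rbind(trials, data.frame(trial = k, depth = cfg$depth,
                                       hidden = cfg$hidden,
                                       ffn_hidden = cfg$ffn_hidden,
                                       ffn_layers = cfg$ffn_layers,
                                       dropout = cfg$dropout,
                                       batch_size = cfg$batch_size,
                                       val_loss = vloss))
    if (is.null(best) || vloss < best$val_loss) {
      best <- list(config = cfg, val_loss = vloss)
    }
  }
  list(config = best$config, trials = trials)
}

#' Extract molecular embeddings from a trained encoder
#'
#' Runs the encoder in evaluation mode (no dropout) and returns the
#' aggregated molecule embeddings (the vector feeding the feedforward head).
#' Deterministic and invariant to atom reindexing.
#'
#' @param model an `mpnn_model`.
#' @param graphs list of `mol_graph` objects (or a `compound_set`).
#' @param ids row ids for the result (defaults to the compound ids).
#' @return a `feature_matrix` of family `GNN` (`hidden` columns).
#' @export
extract_embeddings <- function(model, graphs, ids = NULL) {
  if (inherits(graphs, "compound_set")) {
    if (is.null(ids)) ids <- graphs$id
    graphs <- lapply(graphs$smiles_std, parse_smiles)
  }
  if (is.null(ids)) ids <- as.character(seq_along(graphs))
  bat <- batch_structures(lapply(graphs, build_directed_graph))
  fw <- mpnn_forward(model$weights, bat, model$config)
  m <- fw$Z
  dimnames(m) <- list(ids, sprintf("gnn_%04d", seq_len(ncol(m))))
  feature_matrix(m, family = "GNN")
}

#' Predicted activity probability from the D-MPNN head
#'
#' @param model an `mpnn_model`.
#' @param graphs list of `mol_graph` objects.
#' @return numeric vector of probabilities.
#' @export
predict_mpnn <- function(model, graphs) {
  bat <- batch_structures(lapply(graphs, build_directed_graph))
  fw <- mpnn_forward(model$weights, bat, model$config)
  1 / (1 + exp(-fw$logit))
}
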