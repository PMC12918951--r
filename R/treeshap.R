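# Exact tree-conditional Shapley values for gradient-boosted trees.
#
# Double-precision implementation of the polynomial-time TreeSHAP recursion
# (path extension/unwinding over each decision path, leaf expectations
# weighted by training cover). The library's own single-precision
# contribution output serves as an independent cross-check in the tests; this
# implementation is the one the package reports, because the local-accuracy
# contract (attributions summing to the margin within 1e-6) requires double
# precision.

# Round-trip through IEEE single precision: xgboost stores thresholds and
# compares feature values as float32, so routing must use the same rounding.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          n = length(v), size = 4L)
}

parse_booster_trees <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model$booster)
  dt <- as.data.frame(dt)
  lapply(split(dt, dt$Tree), function(tr) {
    n <- nrow(tr)
    node_of <- function(ids) match(ids, tr$ID)
    list(
      feature = match(tr$Feature, model$features),   # NA for leaves
      # the text dump prints 9 significant digits: enough to round-trip the
      # stored float32 threshold, but only after casting back to float32
      split = as_float32(tr$Split),
      yes = node_of(tr$Yes), no = node_of(tr$No),
      value = tr$Gain,                               # leaf value for leaves
      leaf = tr$Feature == "Leaf",
      cover = tr$Cover)
  })
}

# Expected value of one tree under cover weighting.
tree_expectation <- function(tree, node = 1L) {
  if (tree$leaf[node]) return(tree$value[node])
  wy <- tree$cover[tree$yes[node]]
  wn <- tree$cover[tree$no[node]]
  (wy * tree_expectation(tree, tree$yes[node]) +
     wn * tree_expectation(tree, tree$no[node])) / (wy + wn)
}

tree_leaf_value <- function(tree, x) {
  node <- 1L
  while (!tree$leaf[node]) {
    node <- if (x[tree$feature[node]] < tree$split[node]) tree$yes[node]
            else tree$no[node]
  }
  tree$value[node]
}

# Path bookkeeping for the TreeSHAP recursion. A path is a list of parallel
# vectors: d (feature of the split entering each path element), z (fraction
# of "cold" paths), o (fraction of "hot" paths), w (permutation weights).
path_extend <- function(m, pz, po, pd) {
  l <- length(m$w)
  m$d <- c(m$d, pd); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0L) 1 else 0)
  if (l > 0L) {
    for (i in l:1) {
      m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / (l + 1)
      m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
    }
  }
  m
}

path_unwind <- function(m, i) {
  l <- length(m$w) - 1L
  n <- m$w[l + 1L]
  if (m$o[i] != 0) {
    for (j in l:1) {
      tmp <- m$w[j]
      m$w[j] <- n * (l + 1) / (j * m$o[i])
      n <- tmp - m$w[j] * m$z[i] * (l + 1 - j) / (l + 1)
    }
  } else {
    for (j in l:1) {
      m$w[j] <- m$w[j] * (l + 1) / (m$z[i] * (l + 1 - j))
    }
  }
  keep <- setdiff(seq_len(l + 1L), i)
  m$d <- m$d[keep][seq_len(l)]
  m$z <- m$z[keep][seq_len(l)]
  m$o <- m$o[keep][seq_len(l)]
  m$w <- m$w[seq_len(l)]
  m
}

path_unwound_sum <- function(m, i) {
  l <- length(m$w) - 1L
  total <- 0
  n <- m$w[l + 1L]
  if (m$o[i] != 0) {
    for (j in l:1) {
      tmp <- n * (l + 1) / (j * m$o[i])
      total <- total + tmp
      n <- m$w[j] - tmp * m$z[i] * (l + 1 - j) / (l + 1)
    }
  } else {
    for (j in l:1) {
      total <- total + m$w[j] / (m$z[i] * (l + 1 - j))
    }
    total <- total * (l + 1)
  }
  total
}

treeshap_one_tree <- function(tree, x, p) {
  phi <- numeric(p)
  recurse <- function(node, m, pz, po, pd) {
    m <- path_extend(m, pz, po, pd)
    if (tree$leaf[node]) {
      if (length(m$w) > 1L) {
        for (i in 2:length(m$w)) {
          w <- path_unwound_sum(m, i)
          phi[m$d[i]] <<- phi[m$d[i]] + w * (m$o[i] - m$z[i]) * tree$value[node]
        }
      }
      return(invisible(NULL))
    }
    f <- tree$feature[node]
    hot <- if (x[f] < tree$split[node]) tree$yes[node] else tree$no[node]
    cold <- if (hot == tree$yes[node]) tree$no[node] else tree$yes[node]
    iz <- 1; io <- 1
    k <- match(f, m$d[-1L])
    if (!is.na(k)) {
      k <- k + 1L
      iz <- m$z[k]; io <- m$o[k]
      m <- path_unwind(m, k)
    }
    denom <- tree$cover[node]
    recurse(hot, m, iz * tree$cover[hot] / denom, io, f)
    recurse(cold, m, iz * tree$cover[cold] / denom, 0, f)
  }
  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0L)
  phi
}

# Shapley attributions for every row of `x`; returns list(values, base).
treeshap_values <- function(model, x) {
  trees <- parse_booster_trees(model)
  p <- length(model$features)
  n <- nrow(x)
  expect <- sum(vapply(trees, tree_expectation, numeric(1)))
  # margin offset (global bias): margin minus the summed leaf values
  raw1 <- sum(vapply(trees, tree_leaf_value, numeric(1),
                     x = as_float32(x[1L, ])))
  margin1 <- stats::predict(model$booster,
                            x[1L, , drop = FALSE], outputmargin = TRUE)
  offset <- margin1 - raw1
  phi <- matrix(0, n, p, dimnames = list(rownames(x), model$features))
  for (r in seq_len(n)) {
    xr <- as_float32(x[r, ])
    for (tr in trees) {
      phi[r, ] <- phi[r, ] + treeshap_one_tree(tr, xr, p)
    }
  }
  list(values = phi, base = rep(expect + offset, n))
}

# Double-precision model margin from the parsed trees (used by the
# local-accuracy contract and tests).
booster_margin <- function(model, x) {
  trees <- parse_booster_trees(model)
  raw1 <- sum(vapply(trees, tree_leaf_value, numeric(1),
                     x = as_float32(x[1L, ])))
  margin1 <- stats::predict(model$booster, x[1L, , drop = FALSE],
                            outputmargin = TRUE)
  offset <- margin1 - raw1
  vapply(seq_len(nrow(x)), function(r) {
    offset + sum(vapply(trees, tree_leaf_value, numeric(1),
                        x = as_float32(x[r, ])))
  }, numeric(1))
}
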