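# Structure-aware data partitioning.
#
# Butina sphere-exclusion clustering on Tanimoto distances defines chemical
# neighborhoods; the train/test split and the outer cross-validation folds
# assign whole clusters to one side only, so no structural neighborhood ever
# straddles an evaluation boundary. Bemis-Murcko scaffolds drive the internal
# train/validation/test split of the embedding network.

#' Butina sphere-exclusion clustering
#'
#' Neighbor lists are built at Tanimoto distance (1 - similarity) below
#' `distance_cutoff`; the unassigned compound with the most unassigned
#' neighbors becomes the next cluster centroid (ties broken by lowest input
#' index) and claims its unassigned neighbors; singletons are allowed.
#'
#' @param fps matrix of 0/1 fingerprints (rows = compounds) or a list of bit
#'   vectors.
#' @param distance_cutoff Tanimoto distance threshold in (0, 1); default 0.4.
#' @return a `cluster_assignment`: list with `cluster` (integer id per
#'   compound), `members` (list of index vectors per cluster, centroid
#'   first), and `cutoff`.
#' @export
butina_cluster <- function(fps, distance_cutoff = 0.4) {
  stopifnot(distance_cutoff > 0, distance_cutoff < 1)
  if (is.list(fps)) fps <- do.call(rbind, fps)
  n <- nrow(fps)
  out <- list(cluster = integer(0), members = list(), cutoff = distance_cutoff)
  class(out) <- "cluster_assignment"
  if (is.null(n) || n == 0L) return(out)
  sim <- tanimoto_matrix(fps)
  nbr <- lapply(seq_len(n), function(i) {
    which(1 - sim[i, ] < distance_cutoff & seq_len(n) != i)
  })
  assigned <- logical(n)
  cluster <- integer(n)
  members <- list()
  while (!all(assigned)) {
    counts <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else length(nbr[[i]][!assigned[nbr[[i]]]])
    }, integer(1))
    centroid <- which.max(counts)          # ties -> lowest index
    claim <- c(centroid, nbr[[centroid]][!assigned[nbr[[centroid]]]])
    cid <- length(members) + 1L
    cluster[claim] <- cid
    assigned[claim] <- TRUE
    members[[cid]] <- claim
  }
  out$cluster <- cluster
  out$members <- members
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d compounds in %d clusters (cutoff %.2f)\n",
              length(x$cluster), length(x$members), x$cutoff))
  invisible(x)
}

#' Cluster-respecting train/test split
#'
#' Whole clusters are assigned to the test side greedily (largest first, with
#' seeded shuffling among equal sizes) until the test size is within 2% of
#' the target fraction, preferring assignments that keep the active fraction
#' of both sides within 3 percentage points of the global rate. No cluster
#' ever straddles the boundary.
#'
#' @param assignment a `cluster_assignment`.
#' @param labels binary activity vector aligned with the assignment.
#' @param test_fraction target test fraction (default 0.2).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a `split_plan` with `train_idx`, `test_idx`, `seed` and the
#'   cluster assignment.
#' @export
cluster_train_test_split <- function(assignment, labels, test_fraction = 0.2,
                                     seed = 1L) {
  n <- length(assignment$cluster)
  stopifnot(length(labels) == n, test_fraction > 0, test_fraction < 1)
  members <- assignment$members
  if (length(members) < 2L) {
    stop("Cannot split: a single cluster covers the whole dataset",
         call. = FALSE)
  }
  sizes <- lengths(members)
  target <- test_fraction * n
  global_rate <- mean(labels)
  rng <- local_rng(seed)
  ord <- order(-sizes, sample_local(rng, seq_along(members)))
  test_clusters <- integer(0)
  test_n <- 0; test_act <- 0
  for (cid in ord) {
    if (test_n >= target * 0.98) break
    csize <- sizes[cid]
    cact <- sum(labels[members[[cid]]])
    if (test_n + csize > target * 1.02 && test_n > 0) {
      # only take it if the overshoot still lands nearer the target
      if (abs(test_n + csize - target) > abs(test_n - target)) next
    }
    # prefer clusters that keep the test-side class balance near global
    new_rate <- (test_act + cact) / (test_n + csize)
    if (test_n + csize > 0.5 * target &&
        abs(new_rate - global_rate) > 0.03 &&
        abs(new_rate - global_rate) > abs(test_act / max(test_n, 1) - global_rate)) {
      next
    }
    test_clusters <- c(test_clusters, cid)
    test_n <- test_n + csize
    test_act <- test_act + cact
  }
  test_idx <- sort(unlist(members[test_clusters]))
  train_idx <- setdiff(seq_len(n), test_idx)
  structure(list(train_idx = train_idx, test_idx = test_idx,
                 test_clusters = test_clusters, assignment = assignment,
                 seed = seed, outer_folds = NULL),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / test %d%s (seed %d)\n",
              length(x$train_idx), length(x$test_idx),
              if (!is.null(x$outer_folds))
                sprintf(", %d outer folds", length(x$outer_folds)) else "",
              x$seed))
  invisible(x)
}

#' Stratified group K-fold
#'
#' Groups (clusters) are kept whole: each group lands in exactly one
#' validation fold. Groups are assigned greedily, largest first, to the fold
#' where they least distort the per-fold class ratio relative to the global
#' rate, breaking ties by the emptiest fold and then by fold index.
#'
#' @param ids compound identifiers (used only for the return value).
#' @param labels binary labels.
#' @param groups group (cluster) id per compound.
#' @param k number of folds (>= 2).
#' @param seed integer seed used to shuffle equal-size groups.
#' @return list of `k` folds, each `list(train = ids, val = ids)`.
#' @export
stratified_group_kfold <- function(ids, labels, groups, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(ids) == length(labels),
            length(ids) == length(groups))
  ug <- unique(groups)
  if (length(ug) < k) {
    stop(sprintf("Need at least %d groups for %d folds, got %d", k, k,
                 length(ug)), call. = FALSE)
  }
  gsize <- vapply(ug, function(g) sum(groups == g), integer(1))
  gact <- vapply(ug, function(g) sum(labels[groups == g]), numeric(1))
  gneg <- gsize - gact
  rng <- local_rng(seed)
  ord <- order(-gsize, sample_local(rng, seq_along(ug)))
  fold_act <- numeric(k); fold_neg <- numeric(k)
  fold_of <- integer(length(ug))
  tot_act <- max(sum(gact), 1); tot_neg <- max(sum(gneg), 1)
  # place each group in the fold minimizing the across-fold spread of
  # per-class counts (normalized per class), ties to the smallest fold
  for (gi in ord) {
    eval_f <- vapply(seq_len(k), function(f) {
      aa <- fold_act; nn <- fold_neg
      aa[f] <- aa[f] + gact[gi]; nn[f] <- nn[f] + gneg[gi]
      stats::sd(aa) / tot_act + stats::sd(nn) / tot_neg
    }, numeric(1))
    best <- which(eval_f == min(eval_f))
    if (length(best) > 1L) {
      best <- best[which.min((fold_act + fold_neg)[best])]
    }
    fold_of[gi] <- best[[1L]]
    fold_act[best[[1L]]] <- fold_act[best[[1L]]] + gact[gi]
    fold_neg[best[[1L]]] <- fold_neg[best[[1L]]] + gneg[gi]
  }
  lapply(seq_len(k), function(f) {
    val <- groups %in% ug[fold_of == f]
    list(train = ids[!val], val = ids[val])
  })
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively strips terminal (degree-1) atoms, leaving ring systems and the
#' linkers between them. Acyclic molecules have an empty scaffold, reported
#' as `""`.
#'
#' @param graph a `mol_graph` or standardized SMILES string.
#' @return canonical scaffold SMILES (possibly `""`).
#' @export
murcko_scaffold <- function(graph) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  keep <- rep(TRUE, nrow(graph$atoms))
  repeat {
    g <- subset_graph(graph, keep)
    if (nrow(g$atoms) == 0L) return("")
    term <- g$atoms$degree <= 1L & !g$atoms$in_ring
    if (!any(term)) break
    if (all(term)) return("")
    idx <- which(keep)
    keep[idx[term]] <- FALSE
  }
  smi <- write_smiles(subset_graph(graph, keep))
  can <- ob_canonical(smi)
  if (is.na(can)) smi else can
}

#' Scaffold-binned train/validation/test split
#'
#' Molecules sharing a Bemis-Murcko scaffold always land in the same
#' partition. Scaffold bins are assigned largest-first to the partition that
#' is furthest below its quota; acyclic molecules share one empty-scaffold
#' bin.
#'
#' @param records a `compound_set` (or character vector of standardized
#'   SMILES).
#' @param fractions train/validation/test quotas summing to 1 (default
#'   0.8/0.1/0.1).
#' @param seed integer seed used to shuffle equal-size bins.
#' @return list of three integer index vectors: `train`, `val`, `test`.
#' @export
murcko_scaffold_split <- function(records, fractions = c(0.8, 0.1, 0.1),
                                  seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  smiles <- if (is.character(records)) records else records$smiles_std
  scaf <- vapply(smiles, function(s) murcko_scaffold(s), character(1),
                 USE.NAMES = FALSE)
  bins <- split(seq_along(smiles), scaf)
  sizes <- lengths(bins)
  rng <- local_rng(seed)
  ord <- order(-sizes, sample_local(rng, seq_along(bins)))
  n <- length(smiles)
  quota <- fractions * n
  filled <- numeric(3)
  part_of <- integer(length(bins))
  for (b in ord) {
    deficit <- (quota - filled) / pmax(quota, 1e-9)
    p <- which.max(deficit)
    part_of[b] <- p
    filled[p] <- filled[p] + sizes[b]
  }
  out <- lapply(1:3, function(p) sort(unlist(bins[part_of == p], use.names = FALSE)))
  names(out) <- c("train", "val", "test")
  if (length(out$val) == 0L || length(out$test) == 0L) {
    warning("Scaffold split left an empty partition ",
            "(too few distinct scaffolds)", call. = FALSE)
  }
  out
}

#' Build a nested cross-validation split plan
#'
#' Combines the cluster-respecting train/test split with stratified grouped
#' outer folds over the training portion.
#'
#' @param records a `compound_set` with labels.
#' @param k number of outer folds (default 5).
#' @param test_fraction held-out test fraction (default 0.2).
#' @param distance_cutoff Butina Tanimoto-distance cutoff (default 0.4).
#' @param nbits fingerprint length used for clustering (default 2048).
#' @param seed integer seed.
#' @return a `split_plan` with `train_idx`, `test_idx` and `outer_folds`
#'   (list of `list(train, val)` index vectors into the full record set).
#' @export
build_split_plan <- function(records, k = 5L, test_fraction = 0.2,
                             distance_cutoff = 0.4, nbits = 2048L, seed = 1L) {
  stopifnot(!anyNA(records$label))
  fps <- unclass(fingerprint_matrix(records, nbits = nbits))
  assignment <- butina_cluster(fps, distance_cutoff)
  plan <- cluster_train_test_split(assignment, records$label,
                                   test_fraction, seed)
  tr <- plan$train_idx
  folds <- stratified_group_kfold(tr, records$label[tr],
                                  assignment$cluster[tr], k = k, seed = seed)
  plan$outer_folds <- folds
  plan$k <- k
  audit_split_plan(plan)
  plan
}

# Leakage audit: no cluster may span train/test or two outer folds. Called on
# every constructed plan; also exported for tests and pipelines.

#' Assert that a split plan is leakage-free
#'
#' Checks that no cluster occurs on both sides of the train/test boundary and
#' that no cluster spans two outer validation folds.
#'
#' @param plan a `split_plan`.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
audit_split_plan <- function(plan) {
  cl <- plan$assignment$cluster
  if (length(intersect(cl[plan$train_idx], cl[plan$test_idx])) > 0L) {
    stop("Leakage: cluster spans the train/test boundary", call. = FALSE)
  }
  if (!is.null(plan$outer_folds)) {
    val_cl <- lapply(plan$outer_folds, function(f) unique(cl[f$val]))
    all_val <- unlist(val_cl)
    if (anyDuplicated(all_val)) {
      stop("Leakage: cluster spans two outer validation folds", call. = FALSE)
    }
    covered <- sort(unlist(lapply(plan$outer_folds, `[[`, "val")))
    if (!identical(covered, sort(plan$train_idx))) {
      stop("Outer validation folds must partition the training set",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Seeded RNG that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$seed <- as.integer(seed)
  env
}

sample_local <- function(rng, x, size = length(x)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  rng$seed <- rng$seed + 1L
  sample(x, size)
}
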