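# Shared fixtures, memoised so expensive artifacts (synthetic dataset, split
# plan, fitted pipeline) are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fixture_dataset <- function() {
  memoise_fixture("dataset", function() {
    generate_dataset(synth_config(n = 500, seed = 21))
  })
}

fixture_plan <- function() {
  memoise_fixture("plan", function() {
    build_split_plan(fixture_dataset(), k = 2L, nbits = 256L, seed = 3)
  })
}

fixture_pipeline_config <- function() {
  pipeline_config(nbits = 256L, gnn = mpnn_config(seed = 3), tune_iter = 2L,
                  rfe_step = 0.25, seed = 3)
}

# Final fitted model on the shared dataset (bundle + held-out test report).
fixture_final <- function() {
  memoise_fixture("final", function() {
    fit_final(fixture_dataset(), fixture_plan(),
              config = fixture_pipeline_config())
  })
}

# A small diverse SMILES corpus for chemistry-level tests.
fixture_corpus <- function(n = 200, seed = 5) {
  recs <- generate_molecules(synth_config(n = n, seed = seed))
  recs$smiles_std
}

# Path to the shipped alert catalogs when running from the source tree or the
# installed package.
catalog_path <- function(which) {
  p <- system.file("extdata", paste0(which, "_alerts_subset.tsv"),
                   package = "tdpscreen")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata",
                                  paste0(which, "_alerts_subset.tsv"))
}

python_binary <- function() {
  for (cand in c("python", "python3")) {
    if (nzchar(Sys.which(cand))) return(Sys.which(cand))
  }
  stop("No python interpreter found for the oracle checks")
}

# Serialize graphs for the independent Python fingerprint oracle.
graph_to_json <- function(graph) {
  atomic_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                      Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                      Ca = 20, Fe = 26, Cu = 29, Zn = 30, Se = 34, Br = 35,
                      I = 53)
  z <- unname(atomic_numbers[graph$atoms$element])
  z[is.na(z)] <- 0
  list(atoms = lapply(seq_len(nrow(graph$atoms)), function(a) {
    list(z = z[a], degree = graph$atoms$degree[a],
         charge = graph$atoms$charge[a], nh = graph$atoms$n_h[a],
         ring = as.integer(graph$atoms$in_ring[a]),
         aromatic = as.integer(graph$atoms$aromatic[a]))
  }),
  bonds = lapply(seq_len(nrow(graph$bonds)), function(e) {
    list(i = graph$bonds$i[e], j = graph$bonds$j[e],
         code = if (graph$bonds$aromatic[e]) 4L else graph$bonds$order[e])
  }))
}

# Independent brute-force sphere-exclusion clustering used as the Butina
# oracle (straightforward transcription of the published rules).
brute_force_butina <- function(fps, cutoff) {
  n <- nrow(fps)
  if (n == 0L) return(integer(0))
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- sum(fps[i, ] | fps[j, ])
    sim[i, j] <- if (u == 0) 1 else sum(fps[i, ] & fps[j, ]) / u
  }
  neighbors <- lapply(seq_len(n), function(i)
    setdiff(which(1 - sim[i, ] < cutoff), i))
  cluster <- integer(n)
  cid <- 0L
  while (any(cluster == 0L)) {
    counts <- vapply(seq_len(n), function(i) {
      if (cluster[i] != 0L) return(-1L)
      length(intersect(neighbors[[i]], which(cluster == 0L)))
    }, integer(1))
    centroid <- which(counts == max(counts))[1L]
    cid <- cid + 1L
    members <- c(centroid,
                 intersect(neighbors[[centroid]], which(cluster == 0L)))
    cluster[members] <- cid
  }
  cluster
}
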