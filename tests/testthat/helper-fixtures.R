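# Shared fixtures. Chemistry-backend results are memoized so each backend
# process is started once per test run.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

small_molecules <- function() {
  molecule_table(
    id = c("benzene", "toluene", "naphthalene", "phenol", "ethane",
           "hexane", "pyridine", "chlorobenzene"),
    smiles = c("c1ccccc1", "Cc1ccccc1", "c1ccc2ccccc2c1", "Oc1ccccc1",
               "CC", "CCCCCC", "c1ccncc1", "Clc1ccccc1"))
}

small_descriptors <- function() {
  memo("small_descriptors", compute_descriptors(small_molecules()))
}

small_fingerprints <- function() {
  memo("small_fingerprints", compute_fingerprints(small_molecules()))
}

# dihydropyridine calcium-channel blockers differing in their ester and
# nitrophenyl substitution; the canonical close-analog pair of the screen
nisoldipine_smiles <- function() {
  "CC(C)COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-]"
}
nimodipine_smiles <- function() {
  "COCCOC(=O)C1=C(C)NC(C)=C(C(=O)OC(C)C)C1c1cccc([N+](=O)[O-])c1"
}

dihydropyridine_fps <- function() {
  memo("dhp_fps", compute_fingerprints(molecule_table(
    c("nisoldipine", "nimodipine"),
    c(nisoldipine_smiles(), nimodipine_smiles()))))
}

# small benchmark reused across tests (generation only; no backend)
bench_config <- function() {
  generator_config(seed = 301L, n_candidates = 150L,
                   n_planted_analogs = 25L, n_near_decoys = 10L)
}

small_benchmark <- function() {
  memo("small_benchmark", make_screening_benchmark(bench_config()))
}

# standardized benchmark libraries + descriptors/fingerprints (backend)
small_benchmark_std <- function() {
  memo("small_benchmark_std", {
    bench <- small_benchmark()
    refs <- standardize_library(bench$references[, 1:6])$molecules
    cands <- standardize_library(bench$candidates[, 1:6])$molecules
    list(bench = bench, refs = refs, cands = cands,
         desc_ref = compute_descriptors(refs),
         desc_cand = compute_descriptors(cands),
         fps_ref = compute_fingerprints(refs),
         fps_cand = compute_fingerprints(cands))
  })
}

# independent naive flexible-beta clustering oracle: cluster-to-cluster
# distances are evaluated by direct recursion on the Lance-Williams
# definition over explicit cluster trees (always expanding the later-formed
# cluster), recomputed from scratch at every step -- no incremental matrix
# updates shared with the implementation
naive_flexbeta <- function(d, beta = 0.25) {
  alpha <- (1 - beta) / 2
  n <- nrow(d)
  # cluster = list(key = creation index, a = , b = ) or leaf (key <= n)
  clusters <- lapply(seq_len(n), function(i) list(key = i))
  cdist <- function(x, y) {
    if (x$key <= n && y$key <= n) return(d[x$key, y$key])
    if (y$key > x$key) { tmp <- x; x <- y; y <- tmp }
    alpha * cdist(x$a, y) + alpha * cdist(x$b, y) + beta * cdist(x$a, x$b)
  }
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- cdist(clusters[[i]], clusters[[j]])
        key_pair <- sort(c(clusters[[i]]$key, clusters[[j]]$key))
        better <- is.null(best) || h < best$h - 1e-12 ||
          (abs(h - best$h) <= 1e-12 &&
             (key_pair[1] < best$kp[1] ||
                (key_pair[1] == best$kp[1] && key_pair[2] < best$kp[2])))
        if (better) best <- list(i = i, j = j, h = h, kp = key_pair)
      }
    }
    heights[step] <- best$h
    merged <- list(key = n + step, a = clusters[[best$i]],
                   b = clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions[[step]] <- lapply(clusters, tree_leaves)
  }
  list(heights = heights, partitions = partitions)
}

# leaf membership of a cluster tree from the naive oracle
tree_leaves <- function(tree) {
  if (is.null(tree$a)) return(tree$key)
  sort(c(tree_leaves(tree$a), tree_leaves(tree$b)))
}
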