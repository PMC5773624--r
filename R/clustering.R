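#' Tanimoto distance matrix
#'
#' Pairwise fingerprint distances `D_ij = 1 - TC_ij`, the standard
#' dissimilarity for binary structural keys; zero diagonal, symmetric.
#'
#' @param fps Fingerprint matrix ([compute_fingerprints()]).
#' @return Symmetric numeric distance matrix with compound ids as dimnames.
#' @export
tanimoto_distance_matrix <- function(fps) {
  if (nrow(fps) < 2L) stop("need at least 2 fingerprints")
  d <- 1 - tanimoto_matrix(fps, fps)
  diag(d) <- 0
  d
}

#' Flexible-beta hierarchical clustering
#'
#' Agglomerative clustering with the Lance-Williams flexible-beta update:
#' after merging clusters i and j, the distance from any cluster k to the
#' merged cluster is `alpha * d(k,i) + alpha * d(k,j) + beta * d(i,j)` with
#' `alpha = (1 - beta) / 2` and `gamma = 0`. With the default `beta = 0.25`,
#' `2 * alpha + beta = 1`, the boundary of the monotonicity condition, so
#' merge heights are non-decreasing. Each step merges the pair of active
#' clusters at minimum current distance; ties are broken toward the smallest
#' pair of cluster indices (leaves first, in input order, then merged
#' clusters in creation order), making the result deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g.
#'   [tanimoto_distance_matrix()]).
#' @param beta Flexible-beta parameter in (-1, 1); default 0.25.
#' @return Object of class `flexbeta_hclust` with `merges` (data frame
#'   `cluster_a`, `cluster_b`, `height`, `new_size`; negative entries are
#'   leaves, positive entries earlier merges, as in [stats::hclust()]),
#'   `heights`, `leaf_ids`, and `beta`.
#' @export
flexible_beta_cluster <- function(d, beta = 0.25) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (beta <= -1 || beta >= 1) stop("beta must be in (-1, 1)")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  leaf_ids <- rownames(d)
  if (is.null(leaf_ids)) leaf_ids <- as.character(seq_len(n))
  alpha <- (1 - beta) / 2

  # active clusters keyed 1..n (leaves) then n+1, n+2, ... (merges)
  work <- d
  dimnames(work) <- NULL
  active <- seq_len(n)            # current cluster keys, ascending
  sizes <- rep(1L, n)
  names(sizes) <- active
  merge_mat <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  new_sizes <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    dm <- work
    diag(dm) <- Inf
    best <- which(dm == min(dm), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # ties: smallest (cluster_key_i, cluster_key_j) pair; active is sorted
    # by key, so row-major order on (i, j) indices realizes it
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    ki <- active[i]; kj <- active[j]
    h <- work[i, j]

    newd <- alpha * work[i, ] + alpha * work[j, ] + beta * h
    newd <- newd[-c(i, j)]

    merge_mat[step, ] <- c(ifelse(ki <= n, -ki, ki - n),
                           ifelse(kj <= n, -kj, kj - n))
    heights[step] <- h
    newsize <- sizes[as.character(ki)] + sizes[as.character(kj)]
    new_sizes[step] <- newsize

    keep <- setdiff(seq_len(m), c(i, j))
    work <- work[keep, keep, drop = FALSE]
    work <- rbind(cbind(work, newd), c(newd, 0))
    active <- c(active[keep], n + step)
    sizes[as.character(n + step)] <- newsize
  }

  structure(list(
    merges = data.frame(cluster_a = merge_mat[, 1],
                        cluster_b = merge_mat[, 2],
                        height = heights, new_size = new_sizes),
    heights = heights, leaf_ids = leaf_ids, beta = beta,
    alpha = alpha
  ), class = "flexbeta_hclust")
}

#' @export
print.flexbeta_hclust <- function(x, ...) {
  cat(sprintf(
    "Flexible-beta hierarchical clustering (beta = %.3g, alpha = %.3g)\n",
    x$beta, x$alpha))
  cat(sprintf("  leaves: %d, merges: %d, height range [%.3f, %.3f]\n",
              length(x$leaf_ids), length(x$heights),
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x `flexbeta_hclust` object.
#' @param ... Unused.
#' @return [stats::hclust()] object (usable with [stats::cutree()],
#'   [stats::plot.hclust()], and [ape::as.phylo()]).
#' @export
as.hclust.flexbeta_hclust <- function(x, ...) {
  merge <- as.matrix(x$merges[, c("cluster_a", "cluster_b")])
  dimnames(merge) <- NULL
  hc <- list(merge = merge, height = x$heights,
             order = hclust_leaf_order(merge),
             labels = x$leaf_ids, method = "flexible-beta",
             call = match.call(), dist.method = "tanimoto")
  class(hc) <- "hclust"
  hc
}

hclust_leaf_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into clusters
#'
#' Cuts into exactly `k` clusters, or at a merge height. Labels are
#' canonical: clusters are numbered 1, 2, ... in order of their
#' lexicographically smallest member id, so the labeling is stable under
#' permutation of the input leaves.
#'
#' @param dendrogram `flexbeta_hclust` object.
#' @param k Number of clusters (1 to number of leaves).
#' @param height Alternatively, cut height (clusters = connected groups
#'   merged at or below `height`).
#' @return Named integer vector: cluster label per leaf id.
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, height = NULL) {
  n <- length(dendrogram$leaf_ids)
  if (is.null(k) == is.null(height)) {
    stop("supply exactly one of k or height")
  }
  if (!is.null(k) && (k < 1 || k > n)) stop("k out of range")
  if (!is.null(height) && height < 0) stop("height must be >= 0")
  hc <- stats::as.hclust(dendrogram)
  raw <- if (!is.null(k)) stats::cutree(hc, k = k) else {
    stats::cutree(hc, h = height)
  }
  smallest <- tapply(names(raw), raw, min)  # per raw label, smallest member
  map <- integer(length(smallest))
  map[order(smallest)] <- seq_along(smallest)
  stats::setNames(map[match(raw, as.integer(names(smallest)))], names(raw))
}

#' Export a dendrogram in Newick format
#'
#' Leaf names are compound ids; branch lengths derive from merge-height
#' differences.
#'
#' @param dendrogram `flexbeta_hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the merge table of a dendrogram
#'
#' @param dendrogram `flexbeta_hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merges <- function(dendrogram, path) {
  utils::write.table(dendrogram$merges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
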