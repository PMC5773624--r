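#' Tanimoto coefficient of two fingerprints
#'
#' `TC = n_SAME / (n_A + n_B - n_SAME)` where `n_A` and `n_B` are the
#' numbers of set keys in each fingerprint and `n_SAME` the number of keys
#' set in both. Undefined (error) when both fingerprints are empty.
#'
#' @param fp_a,fp_b 0/1 vectors of equal length (166 for MACCS keys).
#' @return Tanimoto coefficient in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint lengths differ")
  n_a <- sum(fp_a != 0)
  n_b <- sum(fp_b != 0)
  if (n_a == 0 && n_b == 0) stop("Tanimoto undefined for two empty fingerprints")
  n_same <- sum(fp_a != 0 & fp_b != 0)
  n_same / (n_a + n_b - n_same)
}

#' All-pairs Tanimoto coefficients between two fingerprint sets
#'
#' @param fps_a,fps_b Fingerprint matrices (rows = compounds).
#' @return Matrix of Tanimoto coefficients, rows indexed by `fps_a` ids.
#' @export
tanimoto_matrix <- function(fps_a, fps_b = fps_a) {
  a <- unclass(fps_a); b <- unclass(fps_b)
  if (ncol(a) != ncol(b)) stop("fingerprint lengths differ")
  n_a <- rowSums(a)
  n_b <- rowSums(b)
  if (any(n_a == 0) && any(n_b == 0)) {
    stop("Tanimoto undefined for two empty fingerprints")
  }
  n_same <- a %*% t(b)
  tc <- n_same / (outer(n_a, n_b, `+`) - n_same)
  dimnames(tc) <- list(rownames(a), rownames(b))
  tc
}

#' Fingerprint similarity screen
#'
#' A candidate is a hit when its best (maximum) Tanimoto coefficient against
#' the reference fingerprints is at or above the cutoff (boundary
#' inclusive). The hit table records the maximizing reference for each hit.
#'
#' @param references Reference fingerprint set.
#' @param candidates Candidate fingerprint set.
#' @param tc_cutoff Similarity cutoff, default 0.60.
#' @return List with `hit_ids` (sorted) and `hits` (data frame
#'   `candidate_id`, `reference_id`, `tc`).
#' @export
fingerprint_screen <- function(references, candidates, tc_cutoff = 0.60) {
  if (nrow(references) == 0L) stop("empty reference fingerprint set")
  tc <- tanimoto_matrix(candidates, references)
  best <- apply(tc, 1, max)
  best_ref <- colnames(tc)[apply(tc, 1, which.max)]
  hit <- best >= tc_cutoff
  hits <- data.frame(candidate_id = rownames(tc)[hit],
                     reference_id = best_ref[hit],
                     tc = unname(best[hit]),
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$tc, hits$candidate_id), , drop = FALSE]
  rownames(hits) <- NULL
  list(hit_ids = sort(rownames(tc)[hit]), hits = hits)
}

#' Euclidean distance between two score vectors
#'
#' Distance between two compounds in principal-component property space,
#' `sqrt(sum((q_i - p_i)^2))` over the significant components.
#'
#' @param p,q Numeric score vectors of equal length.
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q)) stop("score dimensionalities differ")
  sqrt(sum((q - p)^2))
}

#' Nearest-neighbor screen in PC score space
#'
#' For each reference compound, candidates within `ed_cutoff` (inclusive)
#' are sorted by ascending distance and truncated to `max_neighbors`; ties
#' at the capacity boundary are resolved by candidate-id lexicographic
#' order. The overall hit set is the union of all kept neighbors.
#'
#' @param reference_scores Score matrix of the references.
#' @param candidate_scores Score matrix of the candidates (same PCA model).
#' @param ed_cutoff Distance cutoff, default 5.0.
#' @param max_neighbors Neighbors kept per reference, default 10.
#' @return List with `hit_ids` (sorted) and `neighbors` (data frame
#'   `reference_id`, `candidate_id`, `ed`, `rank`).
#' @export
nearest_neighbor_screen <- function(reference_scores, candidate_scores,
                                    ed_cutoff = 5.0, max_neighbors = 10L) {
  if (nrow(reference_scores) == 0L) stop("empty reference score set")
  if (ncol(reference_scores) != ncol(candidate_scores)) {
    stop("score matrices have different dimensionality; ",
         "use scores from the same PCA model")
  }
  out <- vector("list", nrow(reference_scores))
  cand_t <- t(candidate_scores)
  for (i in seq_len(nrow(reference_scores))) {
    d <- sqrt(colSums((cand_t - reference_scores[i, ])^2))
    sel <- which(d <= ed_cutoff)
    if (length(sel) == 0L) next
    ord <- sel[order(d[sel], rownames(candidate_scores)[sel])]
    ord <- ord[seq_len(min(max_neighbors, length(ord)))]
    out[[i]] <- data.frame(reference_id = rownames(reference_scores)[i],
                           candidate_id = rownames(candidate_scores)[ord],
                           ed = unname(d[ord]),
                           rank = seq_along(ord),
                           stringsAsFactors = FALSE)
  }
  neighbors <- do.call(rbind, out)
  if (is.null(neighbors)) {
    neighbors <- data.frame(reference_id = character(0),
                            candidate_id = character(0),
                            ed = numeric(0), rank = integer(0),
                            stringsAsFactors = FALSE)
  }
  rownames(neighbors) <- NULL
  list(hit_ids = sort(unique(neighbors$candidate_id)), neighbors = neighbors)
}

#' Write a similarity hit table
#'
#' @param hits Hit data frame from [fingerprint_screen()] or
#'   [nearest_neighbor_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
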