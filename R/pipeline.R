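#' Run the full consensus virtual screen
#'
#' Executes the complete protocol: library standardization, 2D descriptors
#' and 166-key fingerprints, the dual typical/atypical initial filtration,
#' the three parallel enrichment methods (fingerprint similarity at
#' `tc_cutoff`, nearest neighbors in PC property space at `ed_cutoff_nn`,
#' and the docking-score gate at one standard deviation above the reference
#' mean), flexible-beta clustering of the structure-based hits with the
#' reference binders, and at-least-`min_votes`-of-3 consensus voting, with
#' optional evaluation against activity labels.
#'
#' The atypical references are those supplied in `atypical_ref_ids`; when
#' omitted they are detected as the reference binders that fall outside the
#' 95% applicability domain of a PCA fitted on the full reference panel
#' (the situation that motivates the parallel atypical filtration branch).
#' The nearest-neighbor property space is a PCA fitted on the references
#' together with the filtered candidates on untransformed unit-variance
#' descriptors; the initial-filtration atypical branch uses log-transformed
#' descriptors, hence its much smaller distance cutoff.
#'
#' @param references Molecule table of reference binders (potency at or
#'   below 10 micromolar; others are dropped with a message).
#' @param candidates Molecule table of the candidate library.
#' @param dock_scores Per-pose docking-score table covering references and
#'   candidates ([read_dock_scores()] layout), or `NULL` to skip the
#'   structure-based method (consensus then runs on the two ligand-based
#'   methods).
#' @param labels Optional activity-label table (`id`, `activity`).
#' @param atypical_ref_ids Optional ids of the atypical references.
#' @param tc_cutoff Fingerprint similarity cutoff, default 0.60.
#' @param ed_cutoff_initial Atypical-branch filtration cutoff, default 1.5.
#' @param ed_cutoff_nn Nearest-neighbor cutoff, default 5.0.
#' @param max_neighbors Neighbors kept per reference, default 10.
#' @param min_votes Consensus vote threshold, default 2.
#' @param cluster_k Optional number of clusters to cut the structure-based
#'   dendrogram into.
#' @return Object of class `ahr_screen`: a list with the standardized
#'   libraries and reports, filtration result, per-method hit sets,
#'   consensus result, dendrogram (and cluster assignment when `cluster_k`
#'   is given), reference docking statistics, and evaluation metrics when
#'   labels are supplied.
#' @export
run_screen <- function(references, candidates, dock_scores = NULL,
                       labels = NULL, atypical_ref_ids = NULL,
                       tc_cutoff = 0.60, ed_cutoff_initial = 1.5,
                       ed_cutoff_nn = 5.0, max_neighbors = 10L,
                       min_votes = 2L, cluster_k = NULL) {
  # --- curation ---------------------------------------------------------
  std_ref <- standardize_library(references)
  std_cand <- standardize_library(candidates)
  refs <- std_ref$molecules
  cands <- std_cand$molecules
  is_binder <- classify_binder(refs$potency_um)
  if (any(is.na(is_binder) | !is_binder)) {
    message(sum(is.na(is_binder) | !is_binder),
            " reference record(s) without binder-level potency dropped")
    refs <- refs[!is.na(is_binder) & is_binder, , drop = FALSE]
  }
  if (nrow(refs) < 3L) stop("too few reference binders after curation")

  # --- descriptors and fingerprints ------------------------------------
  desc_ref <- compute_descriptors(refs)
  desc_cand <- compute_descriptors(cands)
  fps_ref <- compute_fingerprints(refs)
  fps_cand <- compute_fingerprints(cands)

  # --- typical / atypical split ----------------------------------------
  if (is.null(atypical_ref_ids)) {
    pca_all <- suppressWarnings(fit_pca(desc_ref))
    ad_self <- applicability_domain(pca_all, desc_ref)
    atypical_ref_ids <- ad_self$id[!ad_self$inside]
    if (length(atypical_ref_ids) > 0L) {
      message("atypical references (outside the reference-panel domain): ",
              paste(atypical_ref_ids, collapse = ", "))
    }
  }
  atypical_ref_ids <- intersect(atypical_ref_ids, refs$id)
  typical_ids <- setdiff(refs$id, atypical_ref_ids)
  if (length(atypical_ref_ids) == 0L) {
    # no atypical branch possible; fall back to the typical branch only
    atypical_ref_ids <- typical_ids[1]
  }

  # --- initial filtration ----------------------------------------------
  filtration <- initial_filtration(
    desc_ref[typical_ids, , drop = FALSE],
    desc_ref[atypical_ref_ids, , drop = FALSE],
    desc_cand, ed_cutoff_atypical = ed_cutoff_initial)
  filtered_ids <- filtration$union_ids
  if (length(filtered_ids) == 0L) stop("no candidates survived filtration")
  desc_filt <- desc_cand[filtered_ids, , drop = FALSE]
  fps_filt <- fps_cand[filtered_ids, , drop = FALSE]
  class(fps_filt) <- class(fps_cand)

  # --- parallel method 1: fingerprint similarity -----------------------
  fp_screen <- fingerprint_screen(fps_ref, fps_filt, tc_cutoff = tc_cutoff)

  # --- parallel method 2: nearest neighbors in PC space ----------------
  joint <- rbind(desc_ref, desc_filt)
  pca_nn <- suppressWarnings(fit_pca(joint))
  scores <- predict(pca_nn, joint)
  nn_screen <- nearest_neighbor_screen(
    scores[refs$id, , drop = FALSE],
    scores[filtered_ids, , drop = FALSE],
    ed_cutoff = ed_cutoff_nn, max_neighbors = max_neighbors)

  # --- parallel method 3: docking-score gate ---------------------------
  dock <- NULL
  dendrogram <- NULL
  clusters <- NULL
  if (!is.null(dock_scores)) {
    best <- best_pose_per_compound(dock_scores,
                                   expected_ids = c(refs$id, filtered_ids))
    ref_best <- best$best[best$best$compound_id %in% refs$id, , drop = FALSE]
    cand_best <- best$best[best$best$compound_id %in% filtered_ids, ,
                           drop = FALSE]
    stats <- reference_cutoff(ref_best$dg_bind)
    gate <- dock_gate(cand_best, stats)
    dock <- list(stats = stats, gate = gate, failed_ids = best$failed_ids)

    cluster_ids <- union(refs$id, gate$hit_ids)
    if (length(cluster_ids) >= 2L) {
      fps_all <- rbind(unclass(fps_ref), unclass(fps_cand))
      dmat <- tanimoto_distance_matrix(
        structure(fps_all[cluster_ids, , drop = FALSE],
                  class = class(fps_ref)))
      dendrogram <- flexible_beta_cluster(dmat, beta = 0.25)
      if (!is.null(cluster_k)) {
        clusters <- cut_dendrogram(dendrogram, k = cluster_k)
      }
    }
  }

  # --- consensus --------------------------------------------------------
  hit_sets <- list(fingerprint = fp_screen$hit_ids,
                   nearest_neighbor = nn_screen$hit_ids)
  if (!is.null(dock)) hit_sets$docking <- dock$gate$hit_ids
  cons <- consensus(hit_sets, min_votes = min_votes)

  # --- evaluation -------------------------------------------------------
  evaluation <- NULL
  if (!is.null(labels)) {
    if (!is.data.frame(labels)) stop("labels must be a data frame")
    universe <- labels[labels$id %in% filtered_ids &
                         labels$activity %in% c("active", "inactive"), ,
                       drop = FALSE]
    if (nrow(universe) > 0L) {
      per_method <- lapply(hit_sets, function(ids) {
        screen_metrics(confusion(ids, universe))
      })
      cons_metrics <- screen_metrics(confusion(cons$consensus_ids, universe))
      evaluation <- list(universe_size = nrow(universe),
                         n_active = sum(universe$activity == "active"),
                         per_method = per_method,
                         consensus = cons_metrics)
    }
  }

  structure(list(
    references = refs, candidates = cands,
    reports = list(references = std_ref$report,
                   candidates = std_cand$report),
    atypical_ref_ids = atypical_ref_ids,
    filtration = filtration, filtered_ids = filtered_ids,
    fingerprint = fp_screen, nearest_neighbor = nn_screen, docking = dock,
    dendrogram = dendrogram, clusters = clusters,
    consensus = cons, evaluation = evaluation,
    pca_nn = pca_nn
  ), class = "ahr_screen")
}

#' @export
print.ahr_screen <- function(x, ...) {
  cat("Consensus virtual screen\n")
  cat(sprintf("  reference binders: %d (%d atypical)\n",
              nrow(x$references), length(x$atypical_ref_ids)))
  cat(sprintf("  candidates after curation: %d\n", nrow(x$candidates)))
  cat(sprintf(
    "  initial filtration: typical %d + atypical %d -> union %d\n",
    length(x$filtration$typical_ids), length(x$filtration$atypical_ids),
    length(x$filtered_ids)))
  cat(sprintf("  fingerprint hits (TC): %d\n",
              length(x$fingerprint$hit_ids)))
  cat(sprintf("  nearest-neighbor hits (ED): %d\n",
              length(x$nearest_neighbor$hit_ids)))
  if (!is.null(x$docking)) {
    cat(sprintf("  docking-gate hits (cutoff %.1f kcal/mol): %d\n",
                x$docking$stats$cutoff, length(x$docking$gate$hit_ids)))
  }
  cat(sprintf("  consensus (>= %d votes): %d compounds (%d by all methods)\n",
              x$consensus$min_votes, length(x$consensus$consensus_ids),
              length(x$consensus$triple_ids)))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  evaluation universe: %d labeled compounds (%d active)\n",
                x$evaluation$universe_size, x$evaluation$n_active))
    print(x$evaluation$consensus)
  }
  invisible(x)
}
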