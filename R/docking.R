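#' Read a docking-score table
#'
#' Tab-separated with header columns `compound_id`, `stereoisomer_id`,
#' `pose_rank`, `dg_bind_kcal_mol`. Binding free energies are in kcal/mol;
#' more negative means stronger predicted binding.
#'
#' @param path Input path.
#' @return Data frame of per-pose scores.
#' @export
read_dock_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("compound_id", "stereoisomer_id", "pose_rank",
              "dg_bind_kcal_mol")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("dock-score table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_dock_scores(df)
  df
}

validate_dock_scores <- function(df) {
  if (any(!is.finite(df$dg_bind_kcal_mol))) {
    stop("non-finite binding free energy in dock-score table")
  }
  if (any(df$pose_rank < 1)) stop("pose_rank must be >= 1")
  key <- paste(df$compound_id, df$stereoisomer_id, df$pose_rank)
  if (anyDuplicated(key)) {
    stop("pose_rank must be unique within (compound, stereoisomer)")
  }
  invisible(df)
}

#' Best docking pose per compound
#'
#' Selects, for each compound, the pose with the lowest binding free energy
#' over all stereoisomers and poses. Ties between stereoisomers are resolved
#' toward the lexicographically smallest `stereoisomer_id` (then smallest
#' pose rank). Compounds listed in `expected_ids` with no score records are
#' reported as failed in docking and excluded downstream.
#'
#' @param records Per-pose score table (see [read_dock_scores()]).
#' @param expected_ids Optional ids that should have been docked.
#' @return List with `best` (data frame `compound_id`, `stereoisomer_id`,
#'   `pose_rank`, `dg_bind`) and `failed_ids`.
#' @export
best_pose_per_compound <- function(records, expected_ids = NULL) {
  validate_dock_scores(records)
  ord <- order(records$compound_id, records$dg_bind_kcal_mol,
               records$stereoisomer_id, records$pose_rank)
  r <- records[ord, , drop = FALSE]
  first <- !duplicated(r$compound_id)
  best <- data.frame(compound_id = r$compound_id[first],
                     stereoisomer_id = r$stereoisomer_id[first],
                     pose_rank = r$pose_rank[first],
                     dg_bind = r$dg_bind_kcal_mol[first],
                     stringsAsFactors = FALSE)
  rownames(best) <- NULL
  failed <- character(0)
  if (!is.null(expected_ids)) {
    failed <- sort(setdiff(expected_ids, best$compound_id))
    if (length(failed) > 0L) {
      message(length(failed), " compound(s) failed in docking: ",
              paste(utils::head(failed, 5), collapse = ", "),
              if (length(failed) > 5) ", ..." else "")
    }
  }
  list(best = best, failed_ids = failed)
}

#' Reference-based docking-score cutoff
#'
#' Mean and sample standard deviation (n - 1 denominator) of the reference
#' binders' best-pose binding free energies; the gate cutoff is one standard
#' deviation above (i.e. weaker than) the mean, `cutoff = mean + sd` in
#' kcal/mol.
#'
#' @param reference_dgs Numeric best-pose binding free energies (kcal/mol)
#'   of the reference binders.
#' @return Object of class `reference_stats` with `n`, `mean_dg`, `sd_dg`,
#'   `cutoff`.
#' @export
reference_cutoff <- function(reference_dgs) {
  reference_dgs <- as.numeric(reference_dgs)
  if (length(reference_dgs) < 2L) {
    stop("need at least 2 reference binding free energies")
  }
  m <- mean(reference_dgs)
  s <- stats::sd(reference_dgs)
  structure(list(n = length(reference_dgs), mean_dg = m, sd_dg = s,
                 cutoff = m + s),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf(
    "Reference docking scores: n = %d, mean = %.1f, SD = %.1f kcal/mol\n",
    x$n, x$mean_dg, x$sd_dg))
  cat(sprintf("Gate cutoff (mean + 1 SD): %.1f kcal/mol\n", x$cutoff))
  invisible(x)
}

#' Docking-score gate
#'
#' A candidate passes the structure-based gate when its best-pose binding
#' free energy is at or below the reference cutoff (boundary inclusive).
#'
#' @param candidate_best Data frame from [best_pose_per_compound()] (`best`
#'   element) or any table with `compound_id` and `dg_bind`.
#' @param stats Reference statistics from [reference_cutoff()].
#' @return List with `hit_ids` (sorted) and `hits` (gated rows of
#'   `candidate_best`).
#' @export
dock_gate <- function(candidate_best, stats) {
  stopifnot(inherits(stats, "reference_stats"),
            all(c("compound_id", "dg_bind") %in% names(candidate_best)))
  pass <- candidate_best$dg_bind <= stats$cutoff
  hits <- candidate_best[pass, , drop = FALSE]
  rownames(hits) <- NULL
  list(hit_ids = sort(hits$compound_id), hits = hits)
}
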