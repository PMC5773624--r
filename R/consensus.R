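#' Consensus voting over parallel screening methods
#'
#' Fuses the hit sets of the three parallel enrichment methods
#' (fingerprint similarity, nearest neighbors, docking gate) by per-compound
#' vote counting. A compound is a consensus hit when it is selected by at
#' least `min_votes` methods (default 2 of 3).
#'
#' @param hits Named list of character id vectors, one per method; names
#'   must be distinct method labels.
#' @param min_votes Minimum number of methods, default 2.
#' @return Object of class `consensus_result` with `votes` (named integer
#'   vector over all ids seen by any method), `consensus_ids`
#'   (votes >= `min_votes`, sorted), `triple_ids` (selected by every
#'   method), and `min_votes`.
#' @export
consensus <- function(hits, min_votes = 2L) {
  stopifnot(is.list(hits), length(hits) >= 2L)
  if (is.null(names(hits)) || anyDuplicated(names(hits)) ||
      any(!nzchar(names(hits)))) {
    stop("hit sets must carry distinct method labels")
  }
  hits <- lapply(hits, function(x) unique(as.character(x)))
  all_ids <- sort(unique(unlist(hits)))
  votes <- stats::setNames(integer(length(all_ids)), all_ids)
  for (h in hits) votes[h] <- votes[h] + 1L
  structure(list(
    votes = votes,
    consensus_ids = names(votes)[votes >= min_votes],
    triple_ids = names(votes)[votes == length(hits)],
    min_votes = as.integer(min_votes),
    n_methods = length(hits)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d methods (>= %d votes)\n",
              x$n_methods, x$min_votes))
  cat(sprintf("  compounds with >= 1 vote: %d\n", length(x$votes)))
  cat(sprintf("  consensus hits:           %d\n", length(x$consensus_ids)))
  cat(sprintf("  selected by all methods:  %d\n", length(x$triple_ids)))
  invisible(x)
}

#' Confusion counts against activity labels
#'
#' Tallies predictions over a labeled evaluation universe. Compounds labeled
#' `ambiguous` (reported both active and inactive) must be excluded
#' upstream; predicted ids outside the universe are ignored with their count
#' logged.
#'
#' @param predicted Character vector of predicted-positive ids.
#' @param labels Named character vector (`active`/`inactive`) or data frame
#'   with columns `id` and `activity` defining the evaluation universe.
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`,
#'   `n_outside`.
#' @export
confusion <- function(predicted, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$activity, labels$id)
  }
  if (length(labels) == 0L) stop("empty evaluation universe")
  if (!all(labels %in% c("active", "inactive"))) {
    stop("labels must be 'active' or 'inactive'; ",
         "exclude ambiguous compounds upstream")
  }
  predicted <- unique(as.character(predicted))
  n_outside <- sum(!predicted %in% names(labels))
  if (n_outside > 0L) {
    message(n_outside, " predicted id(s) outside the labeled universe ",
            "ignored")
  }
  pred_in <- intersect(predicted, names(labels))
  active <- names(labels)[labels == "active"]
  inactive <- names(labels)[labels == "inactive"]
  structure(list(
    tp = length(intersect(pred_in, active)),
    fp = length(intersect(pred_in, inactive)),
    fn = length(setdiff(active, pred_in)),
    tn = length(setdiff(inactive, pred_in)),
    n_outside = n_outside
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts\n")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Screening evaluation metrics
#'
#' Accuracy `(TP + TN) / (TP + FP + TN + FN)`, sensitivity
#' `TP / (TP + FN)`, and specificity `TN / (TN + FP)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts `confusion_counts` object.
#' @return Object of class `screen_metrics` with `accuracy`, `sensitivity`,
#'   `specificity`, and the counts.
#' @export
screen_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  met <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = met(counts$tp + counts$tn, total),
    sensitivity = met(counts$tp, counts$tp + counts$fn),
    specificity = met(counts$tn, counts$tn + counts$fp),
    counts = counts
  ), class = "screen_metrics")
}

#' Round half away from zero
#'
#' Display rounding used in evaluation summaries (0.005 -> 0.01), unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 2.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @export
print.screen_metrics <- function(x, digits = 2, ...) {
  fmt <- function(v) {
    if (is.na(v)) "undefined" else sprintf("%.*f", digits,
                                           round_half_up(v, digits))
  }
  cat("Screening evaluation\n")
  cat(sprintf("  accuracy:    %s\n", fmt(x$accuracy)))
  cat(sprintf("  sensitivity: %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity: %s\n", fmt(x$specificity)))
  invisible(x)
}

#' Write the votes table of a consensus result
#'
#' @param result `consensus_result` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_votes <- function(result, path) {
  df <- data.frame(id = names(result$votes), votes = unname(result$votes),
                   consensus = names(result$votes) %in% result$consensus_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an activity-label table
#'
#' Tab-separated with header columns `id` and `activity`
#' (`active`/`inactive`/`ambiguous`). Ambiguous records are dropped with a
#' message, mirroring the exclusion of compounds reported both active and
#' inactive.
#'
#' @param path Input path.
#' @return Data frame with columns `id`, `activity`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("id", "activity") %in% names(df)))
  amb <- df$activity == "ambiguous"
  if (any(amb)) {
    message(sum(amb), " ambiguous label(s) excluded from the evaluation ",
            "universe")
    df <- df[!amb, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
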