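#' Fit a PCA model of chemical property space
#'
#' Principal component analysis of a descriptor matrix, the latent-variable
#' model behind the applicability-domain filter and the nearest-neighbor
#' property space. Columns are mean-centered and, by default, scaled to unit
#' variance; constant columns are dropped with a warning before fitting. A
#' component is deemed significant when its eigenvalue (variance of its
#' scores on the unit-variance-scaled data) is at or above 2, i.e. it
#' explains at least two descriptors' worth of variance; at least one
#' component is always retained.
#'
#' The 95% applicability-domain limits stored on the model are
#' \itemize{
#'   \item Hotelling T2: `A (N^2 - 1) / (N (N - A)) * F(0.95; A, N - A)`
#'     with `A` significant components and `N` training compounds;
#'   \item DModX: `sqrt(F(0.95; p - A, (N - A - 1)(p - A)))` on the
#'     normalized residual standard deviation (an F-ratio of the compound
#'     residual variance to the pooled training residual variance).
#' }
#'
#' @param matrix Descriptor matrix (compounds x descriptors).
#' @param scaling `"unit_variance"` (default) or `"none"` (centering only).
#' @param max_pcs Maximum number of components to retain; default keeps all.
#' @param eigenvalue_min Significance threshold on eigenvalues, default 2.
#' @return An object of class `chemspace_pca` with elements
#'   `column_means`, `column_scales`, `loadings` (orthonormal, descriptors x
#'   PCs), `eigenvalues`, `r2x`, `n_significant`, `t2_limit_95`,
#'   `dmodx_crit_95`, `s0` (pooled residual SD), `n_train`, and
#'   `score_variances`.
#' @export
fit_pca <- function(matrix, scaling = c("unit_variance", "none"),
                    max_pcs = NULL, eigenvalue_min = 2) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) < 3L) stop("PCA needs at least 3 compounds")
  constant <- apply(matrix, 2, function(x) diff(range(x)) == 0)
  if (any(constant)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(matrix)[constant], collapse = ", "))
    matrix <- matrix[, !constant, drop = FALSE]
  }
  if (ncol(matrix) < 2L) stop("PCA needs at least 2 non-constant descriptors")

  pc <- stats::prcomp(matrix, center = TRUE,
                      scale. = (scaling == "unit_variance"))
  n <- nrow(matrix)
  p <- ncol(matrix)
  k_max <- min(n - 1L, p, if (is.null(max_pcs)) Inf else max_pcs)
  eig <- pc$sdev^2
  total_var <- sum(eig)
  eig <- eig[seq_len(k_max)]
  loadings <- pc$rotation[, seq_len(k_max), drop = FALSE]
  n_sig <- max(1L, sum(eig >= eigenvalue_min))
  n_sig <- min(n_sig, k_max)

  scales <- if (scaling == "unit_variance") pc$scale else rep(1, p)
  names(scales) <- colnames(matrix)

  # residuals of the n_sig-component model on the training data
  xs <- scale(matrix, center = pc$center, scale = scales)
  scores <- xs %*% loadings
  resid <- xs - scores[, seq_len(n_sig), drop = FALSE] %*%
    t(loadings[, seq_len(n_sig), drop = FALSE])
  dof_resid <- (n - n_sig - 1) * (p - n_sig)
  s0 <- if (dof_resid > 0) sqrt(sum(resid^2) / dof_resid) else 0

  t2_limit <- if (n > n_sig) {
    n_sig * (n^2 - 1) / (n * (n - n_sig)) *
      stats::qf(0.95, n_sig, n - n_sig)
  } else {
    Inf
  }
  dmodx_crit <- if (s0 > 0 && dof_resid > 0 && p > n_sig) {
    sqrt(stats::qf(0.95, p - n_sig, dof_resid))
  } else {
    if (s0 == 0) warning("zero residual variance; DModX limit not defined")
    Inf
  }

  structure(list(
    column_means = stats::setNames(pc$center, colnames(matrix)),
    column_scales = scales,
    loadings = loadings,
    eigenvalues = eig,
    r2x = eig / total_var,
    n_significant = as.integer(n_sig),
    t2_limit_95 = t2_limit,
    dmodx_crit_95 = dmodx_crit,
    s0 = s0,
    n_train = n,
    score_variances = apply(scores, 2, stats::var),
    scaling = scaling
  ), class = "chemspace_pca")
}

#' @export
print.chemspace_pca <- function(x, ...) {
  cat("PCA model of chemical property space\n")
  cat(sprintf("  training compounds: %d, descriptors: %d\n",
              x$n_train, nrow(x$loadings)))
  cat(sprintf("  significant components (eigenvalue >= 2): %d\n",
              x$n_significant))
  r2 <- x$r2x[seq_len(x$n_significant)]
  cat(sprintf("  R2X per significant PC: %s (cumulative %.3f)\n",
              paste(sprintf("%.3f", r2), collapse = ", "), sum(r2)))
  cat(sprintf("  95%% limits: Hotelling T2 = %.3f, DModX = %.3f\n",
              x$t2_limit_95, x$dmodx_crit_95))
  invisible(x)
}

#' @export
summary.chemspace_pca <- function(object, ...) {
  print(object)
  tab <- data.frame(PC = seq_along(object$eigenvalues),
                    eigenvalue = object$eigenvalues,
                    R2X = object$r2x,
                    cumulative_R2X = cumsum(object$r2x))
  cat("\n")
  print(utils::head(tab, 10), row.names = FALSE)
  invisible(tab)
}

check_model_columns <- function(model, matrix) {
  wanted <- names(model$column_means)
  missing <- setdiff(wanted, colnames(matrix))
  if (length(missing) > 0L) {
    stop("descriptor column(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  matrix[, wanted, drop = FALSE]
}

#' Project compounds into a fitted PCA score space
#'
#' Scores are the centered (and scaled) descriptors multiplied by the model
#' loadings, restricted to the significant components.
#'
#' @param object Fitted `chemspace_pca` model.
#' @param matrix Descriptor matrix with (at least) the model's columns.
#' @param n_components Number of components, default the model's
#'   significant count.
#' @param ... Unused.
#' @return Score matrix (compounds x components) with ids as row names.
#' @export
predict.chemspace_pca <- function(object, matrix,
                                  n_components = object$n_significant, ...) {
  matrix <- check_model_columns(object, matrix)
  xs <- scale(matrix, center = object$column_means,
              scale = object$column_scales)
  scores <- xs %*% object$loadings[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(matrix)
  scores
}

#' Alias for projecting compounds into a PCA model
#'
#' @inheritParams predict.chemspace_pca
#' @param model Fitted `chemspace_pca` model.
#' @return Score matrix (see [predict.chemspace_pca()]).
#' @export
project_scores <- function(model, matrix,
                           n_components = model$n_significant) {
  predict(model, matrix, n_components = n_components)
}

#' Applicability-domain membership (Hotelling T2 and DModX)
#'
#' For each compound, Hotelling T2 sums the squared scores over the
#' significant components, each divided by that component's eigenvalue, and
#' DModX is the compound's residual standard deviation off the model plane
#' normalized by the pooled training residual standard deviation. A compound
#' is inside the applicability domain when both statistics are at or below
#' their 95% limits.
#'
#' @param model Fitted `chemspace_pca` model.
#' @param matrix Descriptor matrix.
#' @return Data frame with columns `id`, `t2`, `dmodx`, `inside`.
#' @export
applicability_domain <- function(model, matrix) {
  matrix <- check_model_columns(model, matrix)
  a <- model$n_significant
  xs <- scale(matrix, center = model$column_means,
              scale = model$column_scales)
  load_a <- model$loadings[, seq_len(a), drop = FALSE]
  scores <- xs %*% load_a
  t2 <- drop(scores^2 %*% (1 / model$eigenvalues[seq_len(a)]))
  resid <- xs - scores %*% t(load_a)
  p <- ncol(xs)
  s_i <- sqrt(rowSums(resid^2) / (p - a))
  dmodx <- if (model$s0 > 0) s_i / model$s0 else ifelse(s_i == 0, 0, Inf)
  data.frame(id = rownames(matrix), t2 = t2, dmodx = dmodx,
             inside = t2 <= model$t2_limit_95 & dmodx <= model$dmodx_crit_95,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dual typical/atypical initial filtration
#'
#' First stage of the screen. The typical branch fits a PCA on the binder
#' reference descriptors and keeps candidates inside that model's 95%
#' applicability domain (Hotelling T2 and DModX). The atypical branch, run
#' on log-transformed descriptors, fits a PCA on the atypical references
#' together with all candidates and keeps candidates within Euclidean
#' distance `ed_cutoff_atypical` (boundary inclusive) of any atypical
#' reference in the significant-component score space. The returned union
#' feeds the three parallel enrichment methods.
#'
#' @param binder_desc Descriptor matrix of the binder reference set.
#' @param atypical_desc Descriptor matrix of the (few) atypical references.
#' @param candidate_desc Descriptor matrix of the candidate library (same
#'   registry as the references).
#' @param ed_cutoff_atypical Euclidean-distance cutoff for the atypical
#'   branch, default 1.5.
#' @return List with `typical_ids`, `atypical_ids`, `union_ids`,
#'   `n_overlap`, and the per-branch detail tables `typical_ad` and
#'   `atypical_ed` (minimum distance per candidate).
#' @export
initial_filtration <- function(binder_desc, atypical_desc, candidate_desc,
                               ed_cutoff_atypical = 1.5) {
  if (nrow(binder_desc) == 0L || nrow(atypical_desc) == 0L) {
    stop("reference descriptor sets must be non-empty")
  }
  # typical branch: AD of a PCA fitted on the binder references
  pca_typ <- suppressWarnings(fit_pca(binder_desc))
  cand_typ <- candidate_desc[, colnames(binder_desc), drop = FALSE]
  ad <- applicability_domain(pca_typ, cand_typ)
  typical_ids <- ad$id[ad$inside]

  # atypical branch: log-transformed joint PCA, ED to any atypical reference
  joint <- rbind(atypical_desc, candidate_desc)
  joint_log <- log_transform_joint(joint)
  pca_atyp <- suppressWarnings(fit_pca(joint_log))
  scores <- predict(pca_atyp, joint_log)
  ref_scores <- scores[seq_len(nrow(atypical_desc)), , drop = FALSE]
  cand_scores <- scores[-seq_len(nrow(atypical_desc)), , drop = FALSE]
  dmin <- apply(cand_scores, 1, function(q) {
    min(sqrt(colSums((t(ref_scores) - q)^2)))
  })
  atypical_ids <- rownames(cand_scores)[dmin <= ed_cutoff_atypical]

  union_ids <- sort(union(typical_ids, atypical_ids))
  n_overlap <- length(intersect(typical_ids, atypical_ids))
  message(sprintf(
    "initial filtration: typical %d, atypical %d, overlap %d, union %d",
    length(typical_ids), length(atypical_ids), n_overlap, length(union_ids)))
  list(typical_ids = typical_ids, atypical_ids = atypical_ids,
       union_ids = union_ids, n_overlap = n_overlap,
       typical_ad = ad,
       atypical_ed = data.frame(id = rownames(cand_scores), min_ed = dmin,
                                stringsAsFactors = FALSE, row.names = NULL))
}

log_transform_joint <- function(m) {
  suppressWarnings(log_transform(m))
}

#' Serialize a PCA model to a structured text file
#'
#' @param model `chemspace_pca` model.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  obj <- unclass(model)
  obj$descriptor_names <- names(model$column_means)
  obj$column_means <- unname(model$column_means)
  obj$column_scales <- unname(model$column_scales)
  obj$loadings <- list(values = as.vector(model$loadings),
                       dim = dim(model$loadings),
                       rownames = rownames(model$loadings),
                       colnames = colnames(model$loadings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PCA model written by [write_pca_model()]
#'
#' @param path Input path.
#' @return `chemspace_pca` model.
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(obj$loadings$values, nrow = obj$loadings$dim[1])
  dimnames(loadings) <- list(obj$loadings$rownames, obj$loadings$colnames)
  obj$loadings <- loadings
  obj$column_means <- stats::setNames(as.numeric(obj$column_means),
                                      obj$descriptor_names)
  obj$column_scales <- stats::setNames(as.numeric(obj$column_scales),
                                       obj$descriptor_names)
  obj$descriptor_names <- NULL
  obj$n_significant <- as.integer(obj$n_significant)
  structure(obj, class = "chemspace_pca")
}
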