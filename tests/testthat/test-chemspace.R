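random_descriptor_matrix <- function(n = 50, p = 10, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("d%02d", seq_len(p))))
  m
}

test_that("PCA matches a direct eigendecomposition of the scaled data", {
  x <- random_descriptor_matrix()
  model <- fit_pca(x)

  ev <- eigen(cor(x), symmetric = TRUE)
  expect_equal(model$eigenvalues, ev$values[seq_along(model$eigenvalues)],
               tolerance = 1e-8)
  # loadings agree up to column sign
  for (k in seq_len(ncol(model$loadings))) {
    expect_equal(abs(drop(crossprod(model$loadings[, k], ev$vectors[, k]))),
                 1, tolerance = 1e-8)
  }
  # orthonormality
  g <- crossprod(model$loadings)
  expect_equal(g, diag(ncol(model$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # variance bookkeeping
  expect_true(all(diff(model$eigenvalues) <= 1e-8))
  expect_true(all(model$r2x > 0 & model$r2x <= 1))
  expect_lte(sum(model$r2x), 1 + 1e-8)
  expect_equal(model$n_significant, max(1L, sum(model$eigenvalues >= 2)))
})

test_that("rank-1 data is explained by a single component", {
  set.seed(4)
  t <- rnorm(20)
  x <- cbind(a = 2 * t + 5, b = -3 * t + 1)
  rownames(x) <- sprintf("c%02d", 1:20)
  model <- fit_pca(x)
  expect_equal(model$r2x[1], 1.0, tolerance = 1e-10)
})

test_that("projection is centering, scaling, and rotation", {
  x <- random_descriptor_matrix(n = 30, p = 6, seed = 12)
  model <- fit_pca(x)
  scores <- predict(model, x)

  # training compound projects to its own score row; the mean profile to 0
  mean_profile <- matrix(colMeans(x), 1,
                         dimnames = list("mean", colnames(x)))
  expect_equal(drop(predict(model, mean_profile)),
               rep(0, model$n_significant), tolerance = 1e-10,
               ignore_attr = TRUE)

  # external compound: direct arithmetic oracle
  set.seed(77)
  ext <- matrix(rnorm(6), 1, dimnames = list("ext", colnames(x)))
  hand <- drop(((ext - model$column_means) / model$column_scales) %*%
                 model$loadings[, seq_len(model$n_significant)])
  expect_equal(drop(predict(model, ext)), hand, tolerance = 1e-12,
               ignore_attr = TRUE)

  # full-rank reconstruction recovers the scaled data
  all_scores <- predict(model, x, n_components = ncol(model$loadings))
  recon <- all_scores %*% t(model$loadings)
  xs <- scale(x, center = model$column_means, scale = model$column_scales)
  expect_equal(recon, xs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constant descriptors are dropped with a warning", {
  x <- random_descriptor_matrix(n = 20, p = 4, seed = 3)
  x <- cbind(x, flat = rep(7, 20))
  expect_warning(model <- fit_pca(x), "flat")
  expect_false("flat" %in% names(model$column_means))
  expect_error(fit_pca(x[1:2, ]), "at least 3")
})

test_that("applicability domain matches a first-principles recomputation", {
  x <- random_descriptor_matrix(n = 40, p = 8, seed = 21)
  model <- fit_pca(x)
  set.seed(22)
  y <- matrix(rnorm(25 * 8, sd = 1.4), 25, 8,
              dimnames = list(sprintf("q%02d", 1:25), colnames(x)))
  ad <- applicability_domain(model, y)

  # explicit formulas, recomputed independently of the implementation
  a <- model$n_significant
  ys <- scale(y, center = model$column_means, scale = model$column_scales)
  L <- model$loadings[, seq_len(a), drop = FALSE]
  tt <- ys %*% L
  t2_hand <- rowSums(sweep(tt^2, 2, model$eigenvalues[seq_len(a)], "/"))
  e <- ys - tt %*% t(L)
  s_hand <- sqrt(rowSums(e^2) / (ncol(y) - a))
  xs_train <- scale(x, center = model$column_means,
                    scale = model$column_scales)
  e_train <- xs_train - (xs_train %*% L) %*% t(L)
  s0_hand <- sqrt(sum(e_train^2) /
                    ((nrow(x) - a - 1) * (ncol(x) - a)))
  dmodx_hand <- s_hand / s0_hand
  n <- nrow(x)
  t2_lim <- a * (n^2 - 1) / (n * (n - a)) * qf(0.95, a, n - a)
  dx_lim <- sqrt(qf(0.95, ncol(x) - a, (n - a - 1) * (ncol(x) - a)))

  expect_equal(ad$t2, unname(t2_hand), tolerance = 1e-10)
  expect_equal(ad$dmodx, unname(dmodx_hand), tolerance = 1e-10)
  expect_equal(ad$inside,
               unname(t2_hand <= t2_lim & dmodx_hand <= dx_lim))
})

test_that("training compounds sit inside their own domain at high rate", {
  x <- random_descriptor_matrix(n = 80, p = 12, seed = 55)
  model <- fit_pca(x)
  ad <- applicability_domain(model, x)
  expect_gte(mean(ad$inside), 0.85)

  # a compound at the centroid has T2 of zero and is inside
  centre <- matrix(model$column_means, 1,
                   dimnames = list("centre", names(model$column_means)))
  ad_c <- applicability_domain(model, centre)
  expect_equal(ad_c$t2, 0)
  expect_true(ad_c$inside)

  # a gross outlier is flagged outside
  out <- matrix(model$column_means + 100 * apply(x, 2, sd), 1,
                dimnames = list("far", names(model$column_means)))
  expect_false(applicability_domain(model, out)$inside)
})

test_that("T2 is invariant under orthogonal rotation of the PC basis", {
  x <- random_descriptor_matrix(n = 40, p = 8, seed = 31)
  model <- fit_pca(x)
  a <- model$n_significant
  ys <- scale(x, center = model$column_means, scale = model$column_scales)
  tt <- ys %*% model$loadings[, seq_len(a), drop = FALSE]
  # whiten, rotate by a random orthogonal matrix, unwhiten: T2 unchanged
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(a * a), a)))
  white <- sweep(tt, 2, sqrt(model$eigenvalues[seq_len(a)]), "/")
  t2_rot <- rowSums((white %*% q)^2)
  ad <- applicability_domain(model, x)
  expect_equal(ad$t2, unname(t2_rot), tolerance = 1e-10)
})

test_that("mismatched descriptor columns are rejected with their names", {
  x <- random_descriptor_matrix(n = 20, p = 5, seed = 2)
  model <- fit_pca(x)
  y <- x[, 1:3]
  expect_error(predict(model, y), "d04")
})

test_that("PCA models survive a serialization round trip", {
  x <- random_descriptor_matrix(n = 30, p = 6, seed = 63)
  model <- fit_pca(x)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(back$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_equal(back$n_significant, model$n_significant)
  expect_equal(predict(back, x), predict(model, x), tolerance = 1e-10)
})

test_that("initial filtration unions the branches and logs overlap", {
  std <- small_benchmark_std()
  atyp_ids <- intersect(
    std$bench$references$id[std$bench$references$is_atypical],
    std$refs$id)
  typ_ids <- setdiff(std$refs$id, atyp_ids)
  expect_message(
    fil <- initial_filtration(std$desc_ref[typ_ids, ],
                              std$desc_ref[atyp_ids, ],
                              std$desc_cand),
    "union")
  expect_setequal(fil$union_ids, union(fil$typical_ids, fil$atypical_ids))
  expect_equal(fil$n_overlap,
               length(intersect(fil$typical_ids, fil$atypical_ids)))
  expect_lte(length(fil$union_ids), nrow(std$desc_cand))

  # monotone in the atypical distance cutoff
  fil_wide <- suppressMessages(
    initial_filtration(std$desc_ref[typ_ids, ], std$desc_ref[atyp_ids, ],
                       std$desc_cand, ed_cutoff_atypical = 4))
  expect_true(all(fil$atypical_ids %in% fil_wide$atypical_ids))

  # a candidate structurally identical to a binder scores identically and
  # lands in the typical branch whenever that binder is inside its own AD
  pca_typ <- suppressWarnings(fit_pca(std$desc_ref[typ_ids, ]))
  twin <- std$desc_ref[typ_ids[1], , drop = FALSE]
  rownames(twin) <- "twin"
  ad_twin <- applicability_domain(pca_typ, twin)
  ad_self <- applicability_domain(pca_typ,
                                  std$desc_ref[typ_ids[1], , drop = FALSE])
  expect_equal(ad_twin$inside, ad_self$inside)
  expect_equal(ad_twin$t2, ad_self$t2)
})
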