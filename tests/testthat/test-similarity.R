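test_that("Tanimoto coefficient follows its set-overlap definition", {
  a <- integer(166); a[1:10] <- 1L
  expect_equal(tanimoto(a, a), 1.0)
  b <- integer(166); b[11:20] <- 1L
  expect_equal(tanimoto(a, b), 0.0)
  # n_A = 8, n_B = 6, n_SAME = 4 -> 4 / (8 + 6 - 4)
  p <- integer(166); p[1:8] <- 1L
  q <- integer(166); q[5:10] <- 1L
  expect_equal(tanimoto(p, q), 0.4)
  expect_equal(tanimoto(q, p), 0.4)
  expect_error(tanimoto(integer(166), integer(166)), "undefined")
  expect_error(tanimoto(integer(166), integer(165)), "length")
})

test_that("pairwise Tanimoto matrix matches the scalar definition", {
  set.seed(41)
  fps <- matrix(rbinom(20 * 166, 1, 0.2), 20, 166,
                dimnames = list(sprintf("m%02d", 1:20), NULL))
  fps[rowSums(fps) == 0, 1] <- 1L
  tm <- tanimoto_matrix(fps, fps)
  for (i in c(1, 7, 20)) {
    for (j in c(2, 7, 13)) {
      expect_equal(tm[i, j], tanimoto(fps[i, ], fps[j, ]))
    }
  }
  expect_equal(tm, t(tm))
  expect_equal(unname(diag(tm)), rep(1, 20))
})

test_that("fingerprint screen applies an inclusive cutoff with attribution", {
  # engineered fingerprints with exact best-TC values around the cutoff
  ref <- matrix(0L, 1, 166, dimnames = list("ref", NULL))
  ref[1, 1:10] <- 1L
  cand <- matrix(0L, 3, 166,
                 dimnames = list(c("at_cut", "below", "above"), NULL))
  cand["at_cut", 2:10] <- 1L    # 9 shared / (10 + 9 - 9)  = 0.90
  cand["at_cut", 11:16] <- 1L   # 9 / (10 + 15 - 9)        = 0.5625
  cand["at_cut", 1] <- 1L       # 10 / (10 + 16 - 10)      = 0.625
  cand["below", 1:7] <- 1L
  cand["below", 11:22] <- 1L    # 7 / (10 + 19 - 7)        = 0.318
  cand["above", 1:10] <- 1L     # identical                 = 1
  # exact boundary case: n_A = 10, n_B = 5, n_SAME = 5 gives 0.5; build 0.6:
  # n_SAME = 6, n_B = 6 -> 6 / (10 + 6 - 6) = 0.6
  cand2 <- matrix(0L, 2, 166, dimnames = list(c("exact", "just_under"),
                                              NULL))
  cand2["exact", 1:6] <- 1L
  cand2["just_under", 1:5] <- 1L
  cand2["just_under", 20] <- 1L  # 5 / (10 + 6 - 5) = 0.4545
  res <- fingerprint_screen(ref, rbind(cand, cand2), tc_cutoff = 0.60)
  expect_setequal(res$hit_ids, c("at_cut", "above", "exact"))
  expect_equal(res$hits$reference_id, rep("ref", 3))
  expect_equal(res$hits$tc[res$hits$candidate_id == "exact"], 0.6)

  # raising the cutoff never adds hits
  res_hi <- fingerprint_screen(ref, rbind(cand, cand2), tc_cutoff = 0.8)
  expect_true(all(res_hi$hit_ids %in% res$hit_ids))
  expect_error(fingerprint_screen(ref[0, , drop = FALSE], cand), "empty")
})

test_that("fingerprint screen equals a brute-force all-pairs oracle", {
  std <- small_benchmark_std()
  res <- fingerprint_screen(std$fps_ref, std$fps_cand)
  brute_hits <- character(0)
  for (i in seq_len(nrow(std$fps_cand))) {
    best <- 0
    for (j in seq_len(nrow(std$fps_ref))) {
      best <- max(best, tanimoto(std$fps_cand[i, ], std$fps_ref[j, ]))
    }
    if (best >= 0.60) {
      brute_hits <- c(brute_hits, rownames(std$fps_cand)[i])
    }
  }
  expect_setequal(res$hit_ids, brute_hits)

  # invariance under permutation of references and candidates
  set.seed(5)
  pr <- sample(nrow(std$fps_ref)); pc <- sample(nrow(std$fps_cand))
  res_perm <- fingerprint_screen(std$fps_ref[pr, ], std$fps_cand[pc, ])
  expect_equal(res_perm$hit_ids, res$hit_ids)
})

test_that("Euclidean distance satisfies its definition and metric axioms", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5.0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "dimension")
  set.seed(9)
  for (rep in 1:20) {
    p <- rnorm(5); q <- rnorm(5); r <- rnorm(5)
    expect_equal(euclidean_distance(p, q), sqrt(sum((q - p)^2)),
                 tolerance = 1e-12)
    expect_equal(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("nearest-neighbor screen keeps ten closest with stable ties", {
  # one reference at the origin, 12 candidates inside the cutoff
  ref <- matrix(0, 1, 2, dimnames = list("ref", NULL))
  d <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.2, 3.4, 3.6, 3.8, 4.0, 4.2, 7, 9)
  cand <- cbind(d, 0)
  rownames(cand) <- sprintf("c%02d", seq_along(d))
  res <- nearest_neighbor_screen(ref, cand, ed_cutoff = 5, max_neighbors = 10)
  expect_equal(nrow(res$neighbors), 10L)
  expect_equal(res$neighbors$candidate_id, sprintf("c%02d", 1:10))
  expect_true(all(diff(res$neighbors$ed) >= 0))
  expect_setequal(res$hit_ids, sprintf("c%02d", 1:10))

  # tie at the capacity boundary: lexicographically smaller id wins
  tie <- rbind(cand[1:9, ], zz = c(4.4, 0), aa = c(4.4, 0))
  res_tie <- nearest_neighbor_screen(ref, tie, ed_cutoff = 5,
                                     max_neighbors = 10)
  expect_true("aa" %in% res_tie$neighbors$candidate_id)
  expect_false("zz" %in% res_tie$neighbors$candidate_id)
  # and the result is invariant under input permutation
  res_tie2 <- nearest_neighbor_screen(ref, tie[c(11, 1:9, 10), ],
                                      ed_cutoff = 5, max_neighbors = 10)
  expect_equal(res_tie2$neighbors, res_tie$neighbors)

  # no candidate in range: reference contributes nothing
  far <- matrix(c(100, 100), 1, 2, dimnames = list("far", NULL))
  res_far <- nearest_neighbor_screen(ref, far)
  expect_equal(length(res_far$hit_ids), 0L)
  expect_equal(nrow(res_far$neighbors), 0L)

  expect_error(nearest_neighbor_screen(ref, cand[, 1, drop = FALSE]),
               "dimensionality")
})

test_that("nearest-neighbor screen equals a brute-force oracle", {
  set.seed(23)
  refs <- matrix(rnorm(12 * 3), 12, 3,
                 dimnames = list(sprintf("r%02d", 1:12), NULL))
  cands <- matrix(rnorm(80 * 3, sd = 2), 80, 3,
                  dimnames = list(sprintf("q%02d", 1:80), NULL))
  res <- nearest_neighbor_screen(refs, cands, ed_cutoff = 2,
                                 max_neighbors = 10)
  brute <- character(0)
  for (i in seq_len(nrow(refs))) {
    dd <- apply(cands, 1, function(q) euclidean_distance(refs[i, ], q))
    keep <- names(sort(dd[dd <= 2]))
    brute <- union(brute, utils::head(keep, 10))
  }
  expect_setequal(res$hit_ids, brute)

  # lowering the cutoff never adds hits
  res_small <- nearest_neighbor_screen(refs, cands, ed_cutoff = 1)
  expect_true(all(res_small$hit_ids %in% res$hit_ids))
})
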