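venn_sets <- function(fp_nn = 12, nn_d = 22, fp_d = 0, all3 = 7,
                      fp_total = 32, nn_total = 93, d_total = 177) {
  # build three id sets with prescribed exclusive-region sizes
  mk <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix, seq_len(n))
  else character(0)
  ab <- mk("ab", fp_nn); bc <- mk("bc", nn_d); ac <- mk("ac", fp_d)
  abc <- mk("abc", all3)
  a_only <- mk("a", fp_total - fp_nn - fp_d - all3)
  b_only <- mk("b", nn_total - fp_nn - nn_d - all3)
  c_only <- mk("c", d_total - nn_d - fp_d - all3)
  list(fingerprint = c(a_only, ab, ac, abc),
       nearest_neighbor = c(b_only, ab, bc, abc),
       docking = c(c_only, bc, ac, abc))
}

test_that("consensus reproduces prescribed vote-region sizes", {
  sets <- venn_sets()
  expect_equal(length(sets$fingerprint), 32L)
  expect_equal(length(sets$nearest_neighbor), 93L)
  expect_equal(length(sets$docking), 177L)
  res <- consensus(sets, min_votes = 2)
  expect_equal(length(res$consensus_ids), 41L)
  expect_equal(length(res$triple_ids), 7L)
  expect_true(all(res$triple_ids %in% res$consensus_ids))
})

test_that("consensus equals brute-force membership counting", {
  set.seed(61)
  universe <- sprintf("id%03d", 1:60)
  for (rep in 1:5) {
    sets <- list(m1 = sample(universe, 25), m2 = sample(universe, 30),
                 m3 = sample(universe, 15))
    res <- consensus(sets, min_votes = 2)
    brute <- vapply(universe, function(id) {
      sum(vapply(sets, function(s) id %in% s, logical(1)))
    }, integer(1))
    expect_equal(unname(res$votes[universe[brute > 0]]),
                 unname(brute[brute > 0]))
    expect_setequal(res$consensus_ids, universe[brute >= 2])
    expect_setequal(res$triple_ids, universe[brute == 3])

    # inclusion-exclusion identity for the two-vote set
    pairwise <- union(union(intersect(sets$m1, sets$m2),
                            intersect(sets$m1, sets$m3)),
                      intersect(sets$m2, sets$m3))
    expect_setequal(res$consensus_ids, pairwise)

    # vote-threshold monotonicity
    ids3 <- consensus(sets, min_votes = 3)$consensus_ids
    ids2 <- res$consensus_ids
    ids1 <- consensus(sets, min_votes = 1)$consensus_ids
    expect_true(all(ids3 %in% ids2))
    expect_true(all(ids2 %in% ids1))
  }
})

test_that("consensus input validation catches degenerate calls", {
  expect_equal(length(consensus(list(a = character(0), b = character(0),
                                     c = character(0)))$consensus_ids), 0L)
  expect_error(consensus(list(sprintf("x%d", 1:3), sprintf("x%d", 2:4))),
               "labels")
  expect_error(consensus(list(a = "x", a = "y", b = "z")), "distinct")
})

test_that("confusion counts match an exhaustive tally", {
  set.seed(99)
  universe <- sprintf("u%03d", 1:50)
  labels <- setNames(sample(c("active", "inactive"), 50, replace = TRUE),
                     universe)
  for (rep in 1:5) {
    pred <- sample(universe, sample(0:50, 1))
    cc <- confusion(pred, labels)
    tally <- table(factor(universe %in% pred, c(TRUE, FALSE)),
                   factor(labels, c("active", "inactive")))
    expect_equal(cc$tp, unname(tally["TRUE", "active"]))
    expect_equal(cc$fp, unname(tally["TRUE", "inactive"]))
    expect_equal(cc$fn, unname(tally["FALSE", "active"]))
    expect_equal(cc$tn, unname(tally["FALSE", "inactive"]))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 50L)
  }

  # boundary predictions
  act <- names(labels)[labels == "active"]
  perfect <- confusion(act, labels)
  expect_equal(perfect$fp, 0L); expect_equal(perfect$fn, 0L)
  none <- confusion(character(0), labels)
  expect_equal(none$tp, 0L); expect_equal(none$fn, length(act))

  # ids outside the universe are ignored but logged
  expect_message(out <- confusion(c(act[1], "stranger"), labels),
                 "outside")
  expect_equal(out$n_outside, 1L)
  expect_error(confusion("x", setNames(character(0), character(0))),
               "empty")
  expect_error(confusion("x", c(a = "active", b = "maybe")), "ambiguous")
})

test_that("metrics follow their formulas and handle zero denominators", {
  counts <- structure(list(tp = 20L, fp = 1L, tn = 55L, fn = 18L,
                           n_outside = 0L), class = "confusion_counts")
  m <- screen_metrics(counts)
  expect_equal(m$sensitivity, 20 / 38)
  expect_equal(round_half_up(m$sensitivity, 2), 0.53)
  expect_equal(m$specificity, 55 / 56)
  expect_equal(m$accuracy, 75 / 94)

  even <- structure(list(tp = 1L, fp = 1L, tn = 1L, fn = 1L,
                         n_outside = 0L), class = "confusion_counts")
  me <- screen_metrics(even)
  expect_equal(me$accuracy, 0.5)
  expect_equal(me$sensitivity, 0.5)
  expect_equal(me$specificity, 0.5)

  no_neg <- structure(list(tp = 3L, fp = 0L, tn = 0L, fn = 1L,
                           n_outside = 0L), class = "confusion_counts")
  expect_true(is.na(screen_metrics(no_neg)$specificity))

  # accuracy is the prevalence-weighted blend of sensitivity/specificity
  set.seed(7)
  for (rep in 1:10) {
    cc <- structure(as.list(setNames(sample(1:40, 4, replace = TRUE),
                                     c("tp", "fp", "tn", "fn"))),
                    class = "confusion_counts")
    cc$n_outside <- 0L
    mm <- screen_metrics(cc)
    n_pos <- cc$tp + cc$fn; n_neg <- cc$tn + cc$fp
    blend <- (n_pos * mm$sensitivity + n_neg * mm$specificity) /
      (n_pos + n_neg)
    expect_equal(mm$accuracy, blend, tolerance = 1e-12)
  }
})

test_that("rounding for reports is half away from zero", {
  expect_equal(round_half_up(0.525, 2), 0.53)
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(0.8649, 2), 0.86)
})

test_that("label tables exclude ambiguous records on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tactivity", "a\tactive", "b\tinactive", "c\tambiguous"),
             path)
  expect_message(lab <- read_labels(path), "ambiguous")
  expect_equal(lab$id, c("a", "b"))
})
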