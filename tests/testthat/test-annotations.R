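test_that("reaction-time correction shifts, clamps and guards idempotence", {
  ann <- observer_annotations(c("a", "a", "b"), "run1", c(10.9, 20.9, 0.5))
  out <- correct_rt(ann, rt = 0.9)
  expect_equal(sort(out$press_time_s), c(0.0, 10.0, 20.0))
  expect_true(attr(out, "rt_corrected"))
  expect_error(correct_rt(out, 0.9), "already")

  ident <- correct_rt(observer_annotations("a", "r", c(1, 2)), rt = 0)
  expect_equal(ident$press_time_s, c(1, 2))
})

test_that("pass-1 merging chains presses within 1 TR and averages times", {
  ann <- observer_annotations(c("a", "b", "c"), "run1", c(10.0, 10.8, 12.1),
                              rt_corrected = TRUE)
  b <- merge_boundaries(ann, tr = 2.47)
  expect_equal(nrow(b), 1L)
  expect_equal(b$time, mean(c(10.0, 10.8, 12.1)), tolerance = 1e-12)
  expect_equal(b$n_observers, 3L)
})

test_that("an observer pressing twice in one cluster is counted once", {
  ann <- observer_annotations(c("a", "a", "b"), "run1", c(9.8, 10.2, 10.4),
                              rt_corrected = TRUE)
  b <- merge_boundaries(ann, tr = 2)
  expect_equal(b$n_observers, 2L)
  # observer a's two presses are averaged first (10.0), then averaged with b
  expect_equal(b$time, mean(c(10.0, 10.4)))
})

test_that("pass-2 merges adjacent multi-observer boundaries under 2 TRs once", {
  # pass 1 yields clusters {9,10,11} (n=3) and {13.5,14.5} (n=2) at TR 2.47;
  # gap 4.0 < 2 TR = 4.94 and both have >= 2 observers -> merged
  ann <- observer_annotations(c("a", "b", "c", "d", "e"), "run1",
                              c(9, 10, 11, 13.5, 14.5), rt_corrected = TRUE)
  b <- merge_boundaries(ann, tr = 2.47)
  expect_equal(nrow(b), 1L)
  expect_equal(b$time, mean(c(9, 10, 11, 13.5, 14.5)))
  expect_equal(b$n_observers, 5L)

  # gap at exactly >= 2 TR stays apart
  ann2 <- observer_annotations(c("a", "b", "c", "d"), "run1",
                               c(9.9, 10.1, 14.9, 15.1), rt_corrected = TRUE)
  b2 <- merge_boundaries(ann2, tr = 2)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$n_observers, c(2L, 2L))

  # singleton (n = 1) boundaries never participate in pass 2
  ann3 <- observer_annotations(c("a", "b", "c"), "run1",
                               c(9.9, 10.1, 13.0), rt_corrected = TRUE)
  b3 <- merge_boundaries(ann3, tr = 2)
  expect_equal(nrow(b3), 2L)
})

test_that("pass 2 runs once, not to convergence (no long chains)", {
  # three clusters, each n = 2, consecutive gaps both < 2 TR: only the first
  # pair merges; the merged boundary is not re-merged with the third
  ann <- observer_annotations(rep(c("a", "b"), 3), "run1",
                              c(10.0, 10.2, 13.0, 13.2, 16.0, 16.2),
                              rt_corrected = TRUE)
  b <- merge_boundaries(ann, tr = 2)
  expect_equal(nrow(b), 2L)
  expect_equal(b$n_observers, c(4L, 2L))
})

test_that("merging is invariant to observer order and ids, presses conserved", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    ann <- observer_annotations(sample(letters[1:6], n, TRUE), "run1",
                                sort(runif(n, 0, 300)), rt_corrected = TRUE)
    b <- merge_boundaries(ann, tr = 2.2)
    # permute rows and relabel observers
    perm <- sample(nrow(ann))
    relab <- setNames(sample(LETTERS[1:6]), letters[1:6])
    ann2 <- observer_annotations(relab[ann$observer_id[perm]], "run1",
                                 ann$press_time_s[perm], rt_corrected = TRUE)
    b2 <- merge_boundaries(ann2, tr = 2.2)
    expect_equal(b$time, b2$time)
    expect_equal(b$n_observers, b2$n_observers)
    expect_lte(sum(b$n_observers), nrow(ann))
  }
})

test_that("run-end boundaries are dropped", {
  b <- data.frame(run_id = "run1", time = c(100, 589, 595),
                  n_observers = c(5L, 5L, 5L), salience_bin = NA)
  out <- drop_run_end(b, run_duration = 600, margin = 10)
  expect_equal(out$time, c(100, 589))
  expect_equal(nrow(drop_run_end(b[0, ], 600)), 0L)
})

test_that("threshold selection matches hand enumeration with lower-k ties", {
  # tallies {4:4, 5:6, 6:15}: counts k<=4 -> 25, k5 -> 21, k6 -> 15; mean 20
  b <- boundaries_from_tally(c(`4` = 4, `5` = 6, `6` = 15))
  ann <- observer_annotations(rep(c("x", "y"), each = 20), "run1",
                              rep(seq_len(20) * 5, 2), rt_corrected = TRUE)
  expect_equal(nrow(ann) / 2, 20)
  expect_equal(select_threshold(b, ann), 5L)

  # strictly decreasing counts with a tie between k=5 (22) and k=6 (20) at
  # mean 21 -> lower k wins
  b2 <- boundaries_from_tally(c(`1` = 5, `2` = 3, `3` = 2, `4` = 2,
                                `5` = 2, `6` = 20))
  ann2 <- observer_annotations(rep(c("x", "y"), each = 21), "run1",
                               rep(seq_len(21) * 5, 2), rt_corrected = TRUE)
  expect_equal(select_threshold(b2, ann2), 5L)

  # degenerate total agreement: every k yields the same count -> k = 1
  b3 <- boundaries_from_tally(c(`8` = 12))
  ann3 <- observer_annotations(rep(letters[1:8], each = 12), "run1",
                               rep(seq_len(12) * 10, 8), rt_corrected = TRUE)
  expect_equal(select_threshold(b3, ann3), 1L)
})

test_that("thresholding retains only boundaries with enough observers", {
  b <- boundaries_from_tally(c(`3` = 5, `5` = 4, `9` = 2))
  out <- apply_threshold(b, 5)
  expect_true(all(out$n_observers >= 5))
  expect_equal(nrow(out), 6L)
})

test_that("salience binning balances counts and flags degenerate input", {
  b <- boundaries_from_tally(c(`5` = 4, `6` = 4, `7` = 4))
  out <- bin_salience(b)
  expect_equal(unname(table(out$salience_bin)[c("low", "med", "high")]),
               rep(4L, 3), ignore_attr = TRUE)
  expect_false(attr(out, "degenerate"))
  expect_equal(sum(table(out$salience_bin)), nrow(b))

  b1 <- boundaries_from_tally(c(`7` = 6))
  out1 <- bin_salience(b1)
  expect_true(attr(out1, "degenerate"))
  expect_equal(unique(out1$salience_bin), "low")
})

test_that("full consensus chain recovers ground truth under perfect observers", {
  gt <- ground_truth(c(30, 80, 150, 220, 290, 350), run_length = 420,
                     tr = 2, salience_prob = 1, n_observers = 8)
  ann <- simulate_observers(gt, rt_mean = 0.9, rt_jitter = 0, seed = 4)
  b <- consensus_boundaries(ann, tr = 2, rt = 0.9, run_duration = 420)
  expect_equal(nrow(b), 6L)
  expect_equal(b$time, gt$boundary_times$run1, tolerance = 1e-9)
  expect_true(all(b$n_observers == 8L))
})

test_that("observer-group comparison: identical groups match fully", {
  times <- c(25, 70, 130, 200, 260, 320)
  a <- correct_rt(perfect_annotations(times, n_observers = 6))
  b <- correct_rt(perfect_annotations(times, n_observers = 6))
  res <- compare_observer_groups(a, b, tr = 2, n_perm = 30, seed = 9)
  expect_equal(res$match, nrow(res$boundaries_a))
  expect_gte(res$p_lower, 0) # duplicated observers: random splits match too
  res2 <- compare_observer_groups(a, b, tr = 2, n_perm = 30, seed = 9)
  expect_identical(res$null, res2$null)
  expect_identical(res$p_lower, res2$p_lower)
})
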