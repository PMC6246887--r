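test_that("canonical HRF peaks where the double-gamma mode lies", {
  spec <- hrf_spec()
  h <- canonical_hrf(spec, tr = 2)
  # dense numeric maximization of the double-gamma itself (independent oracle)
  dg <- function(t) dgamma(t, shape = 6, scale = 1) -
    (1 / 6) * dgamma(t, shape = 16, scale = 1)
  t_star <- optimize(dg, c(0, 12), maximum = TRUE)$maximum
  expect_lt(abs(h$times[which.max(h$kernel)] - t_star), h$dt + 1e-9)
  expect_equal(h$kernel[1], 0)
  expect_equal(max(h$kernel), 1)
  # no undershoot -> pure positive gamma, no negative lobe
  h0 <- canonical_hrf(hrf_spec(undershoot_ratio = 0), tr = 2)
  expect_true(all(h0$kernel >= 0))
  expect_error(hrf_spec(kernel_length = 12), "24")
})

test_that("design construction covers the three schemes", {
  d0 <- build_design(numeric(0), 100, 2)
  expect_length(d0$event_cols, 0)
  expect_true("const" %in% colnames(d0$X))
  expect_true(any(grepl("^cos", colnames(d0$X))))

  d1s <- build_design(50, 100, 2, scheme = "single")
  d1p <- build_design(50, 100, 2, scheme = "per-boundary")
  expect_equal(unname(d1s$X[, d1s$event_cols]),
               unname(d1p$X[, d1p$event_cols]))

  # two boundaries 1.5 s apart (inside the 6 s exclusion zone): per-boundary
  # columns nearly collinear
  d2 <- build_design(c(50, 51.5), 100, 2, scheme = "per-boundary")
  cc <- cor(d2$X[, d2$event_cols[1]], d2$X[, d2$event_cols[2]])
  expect_gt(cc, 0.8)

  # same microtime bin -> unresolvable
  expect_error(build_design(c(50, 50.001), 100, 2, scheme = "per-boundary"),
               "microtime")
})

test_that("amplitude estimation recovers signals and absorbs drift", {
  spec <- hrf_spec()
  d <- build_design(c(40, 120, 200), 150, 2, spec, scheme = "single")
  ev <- d$X[, "events"]
  drift <- 3 * d$X[, "cos1"]
  est <- estimate_amplitude(2 * ev + drift, d)
  expect_equal(unname(est$beta), 2, tolerance = 1e-10)

  # signal orthogonal to events
  est0 <- estimate_amplitude(drift, d)
  expect_equal(unname(est0$beta), 0, tolerance = 1e-10)

  # amplitude invariant to adding anything in the cosine span
  set.seed(21)
  y <- 1.5 * ev + rnorm(150, 0, 0.2)
  b1 <- estimate_amplitude(y, d)$beta
  b2 <- estimate_amplitude(y + 7 * d$X[, "cos2"], d)$beta
  expect_equal(unname(b1), unname(b2), tolerance = 1e-10)

  # rank deficiency is named
  dd <- build_design(50, 100, 2)
  dd$X <- cbind(dd$X, dup = dd$X[, "events"])
  expect_error(estimate_amplitude(rnorm(100), dd), "dup")
})

test_that("single-trial betas recover amplitudes and apply the 6 s exclusion", {
  gt <- ground_truth(c(40, 100, 170), 240, tr = 2, amplitudes = c(1, 2, 3),
                     n_participants = 1)
  sim <- simulate_bold(gt, noise_sd = 0, ar1 = 0, drift_amp = 0)
  b <- data.frame(run_id = "run1", time = c(40, 100, 170),
                  n_observers = c(5L, 8L, 12L), salience_bin = "low")
  tab <- single_trial_betas(sim$tcs, b, tr = 2)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$beta, c(1, 2, 3), tolerance = 1e-8)

  # both members of close pairs are dropped: 161 -> 157 bookkeeping
  times161 <- c(seq(10, 20, length.out = 4), seq(40, 4000, length.out = 157))
  expect_equal(sum(boundary_gap_keep(times161, 6)), 157L)
  # no close pairs -> unchanged
  times19 <- seq(20, 470, length.out = 19)
  expect_equal(sum(boundary_gap_keep(times19, 6)), 19L)
})

test_that("single-column beta is the mean of isolated per-boundary betas", {
  gt <- ground_truth(c(50, 130, 210), 300, tr = 2, amplitudes = c(1, 2, 3),
                     n_participants = 1)
  sim <- simulate_bold(gt, noise_sd = 0, ar1 = 0, drift_amp = 0)
  tc <- sim$tcs$p001$run1
  ds <- build_design(gt$boundary_times$run1, 150, 2, scheme = "single")
  dp <- build_design(gt$boundary_times$run1, 150, 2, scheme = "per-boundary")
  bs <- estimate_amplitude(tc, ds)$beta
  bp <- estimate_amplitude(tc, dp)$beta
  expect_equal(unname(bs), mean(bp), tolerance = 0.02)
})

test_that("FIR deconvolution recovers the response shape and ordering", {
  spec <- hrf_spec()
  # flat signal -> flat zero curves
  flat <- list(roi_tc(rep(0, 200) + c(1e-8, rep(0, 199)), tr = 1))
  bz <- data.frame(run_id = "run1", time = c(50, 120), n_observers = 5L,
                   salience_bin = "low")
  fz <- fir_timecourse(flat, bz, tr = 1)
  expect_lt(max(abs(fz$mean)), 1e-6)

  # isolated event at TR resolution 1 s: FIR curve ~ HRF samples
  h <- canonical_hrf(spec, tr = 1)
  times <- c(60, 120, 180)
  y <- filmseg:::convolve_sticks(times, rep(1, 3), 240, 1, spec)
  fir <- fir_timecourse(list(roi_tc(y, tr = 1)),
                        data.frame(run_id = "run1", time = times,
                                   n_observers = 5L, salience_bin = "all"),
                        tr = 1)
  curve <- fir$mean[1, ]
  # each FIR bin covers one second; compare at bin midpoints
  hrf_at <- approx(h$times, h$kernel, xout = pmax(fir$lags + 0.5, 0),
                   rule = 2)$y
  hrf_at[fir$lags + 0.5 < 0] <- 0
  expect_lt(max(abs(curve - hrf_at)), 0.12)
  # FIR and canonical GLM agree on peak amplitude within 15 %
  d <- build_design(times, 240, 1, spec, scheme = "single")
  amp <- unname(estimate_amplitude(y, d)$beta)
  expect_lt(abs(max(curve) - amp * max(h$kernel)) / (amp * max(h$kernel)),
            0.15)

  # salience-ordered amplitudes give ordered FIR peaks
  gt <- ground_truth(seq(30, 450, by = 42), 480, tr = 2,
                     amplitudes = rep(c(1, 2, 3), length.out = 11),
                     n_participants = 6)
  sim <- simulate_bold(gt, noise_sd = 0.3, ar1 = 0, drift_amp = 0, seed = 23)
  bins <- rep(c("low", "med", "high"), length.out = 11)
  bd <- data.frame(run_id = "run1", time = gt$boundary_times$run1,
                   n_observers = 5L, salience_bin = bins)
  fr <- fir_timecourse(lapply(sim$tcs, `[[`, "run1"), bd, tr = 2)
  peaks <- apply(fr$mean, 1, max)
  expect_lt(peaks["low"], peaks["med"])
  expect_lt(peaks["med"], peaks["high"])
})
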