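test_that("IMED matches the dense quadratic-form oracle and is a pseudometric", {
  set.seed(51)
  for (rep in 1:3) {
    a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
    # 5x5 frames: the 9x9 window covers every pixel pair, so truncated and
    # full-G agree exactly
    expect_equal(imed(a, b), dense_imed(a, b), tolerance = 1e-6)
    expect_equal(imed(a, b), imed(b, a))
    expect_equal(imed(a, a), 0)
    expect_gte(imed(a, b), 0)
  }
  # RGB: per-channel quadratic forms summed
  ar <- array(runif(5 * 5 * 3), c(5, 5, 3))
  br <- array(runif(5 * 5 * 3), c(5, 5, 3))
  expect_equal(imed(ar, br), dense_imed(ar, br), tolerance = 1e-6)
  expect_error(imed(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("IMNCC matches its dense oracle with the expected limits", {
  set.seed(52)
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  expect_equal(imncc(a, b), dense_imncc(a, b), tolerance = 1e-6)
  expect_equal(imncc(a, a), 1)
  ac <- a - mean(a)
  expect_equal(imncc(ac, -ac), -1)
})

test_that("truncated neighborhood converges to the full-G form as it grows", {
  set.seed(53)
  a <- matrix(runif(100), 10, 10); b <- matrix(runif(100), 10, 10)
  full <- dense_imed(a, b, sigma = 2, radius = Inf)
  errs <- vapply(c(2, 4, 6, 9), function(r)
    abs(imed(a, b, sigma = 2, radius = r) - full), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-8)
})

test_that("histogram distance is spatially invariant and hand-checkable", {
  set.seed(54)
  a <- matrix(runif(64), 8, 8)
  perm <- matrix(sample(a), 8, 8)
  expect_equal(hist_distance(a, perm), 0)
  expect_equal(hist_distance(a, a), 0)
  # 2x2 toy with 2 bins: counts (2,2) vs (1,3) -> distance sqrt(2)
  f1 <- matrix(c(0.1, 0.1, 0.6, 0.6), 2, 2)
  f2 <- matrix(c(0.1, 0.6, 0.6, 0.6), 2, 2)
  expect_equal(hist_distance(f1, f2, n_bins = 2), sqrt(2))
})

test_that("luminance difference is the absolute mean difference", {
  a <- matrix(0.3, 4, 4); b <- matrix(0.5, 4, 4)
  expect_equal(luminance_diff(a, b), 0.2)
  expect_equal(luminance_diff(a, a), 0)
  set.seed(55)
  x <- matrix(runif(16), 4, 4); y <- matrix(runif(16), 4, 4)
  expect_equal(luminance_diff(x, y), abs(mean(x) - mean(y)))
})

test_that("window maximization finds the most-changed cross pair", {
  base <- matrix(0.5, 4, 4)
  odd <- matrix(0.9, 4, 4)
  frames <- list(base, base, base, odd, base, base)
  times <- c(-0.8, -0.4, 0, 0.2, 0.4, 0.8) + 2 # boundary at 2
  d <- window_change(frames, times, 2, luminance_diff, mode = "max-dist")
  expect_equal(d, 0.4) # the single changed post frame drives the max
  cc <- window_change(frames, times, 2,
                      function(a, b) imncc(a + 1e-6 * seq_len(16),
                                           b + 1e-6 * seq_len(16)),
                      mode = "min-corr")
  expect_lte(cc, 1)

  # static scene
  fs <- list(base, base, base, base)
  ts <- c(1.2, 1.7, 2.2, 2.7)
  expect_equal(window_change(fs, ts, 2, luminance_diff, mode = "max-dist"), 0)

  # window beyond run start: truncated, no error
  expect_false(is.na(window_change(fs, ts, 1.5, luminance_diff, mode = "max-dist")))
})

test_that("PSD measures separate tones and agree across identical epochs", {
  rate <- 8000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  same <- sin(2 * pi * 440 * t)
  r <- psd_measures(same, rate, 1)
  expect_gt(r$psd_corr, 0.999)
  expect_lt(r$psd_dist, 1e-6 * max(abs(same)))

  # distinct tones on either side
  mix <- ifelse(t < 1, sin(2 * pi * 440 * t), sin(2 * pi * 2000 * t))
  r2 <- psd_measures(mix, rate, 1)
  expect_lt(r2$psd_corr, 0.1)

  # white noise with matched variance: long epochs correlate on the shape
  set.seed(56)
  wn <- rnorm(2 * rate)
  r3 <- psd_measures(wn, rate, 1, epoch = 1)
  expect_gt(r3$psd_corr, -0.2) # flat spectra: correlation fluctuates near 0
})

test_that("volume change is the absolute RMS difference", {
  rate <- 1000
  audio <- c(rep(0.1, 500), rep(0.3, 500))
  expect_equal(volume_diff(audio, rate, 0.5), 0.2)
  expect_equal(volume_diff(rep(0, 1000), rate, 0.5), 0)
  set.seed(57)
  ramp <- runif(1000, -1, 1) * seq(0, 1, length.out = 1000)
  pre <- ramp[401:500]; post <- ramp[501:600]
  expect_equal(volume_diff(ramp, rate, 0.5),
               abs(sqrt(mean(pre^2)) - sqrt(mean(post^2))))
  expect_equal(volume_diff(ramp, rate, 0.5, type = "mean-abs"),
               abs(mean(abs(pre)) - mean(abs(post))))
})

test_that("layered feature correlations have the layer contract", {
  ex <- pyramid_extractor(3)
  f <- matrix(runif(64), 8, 8)
  frames <- list(f, f)
  times <- c(1.5, 2.5)
  v <- layered_feature_corr(frames, times, 2, ex)
  expect_length(v, 3)
  expect_equal(v, rep(1, 3), tolerance = 1e-10)

  # hand-computed oracle on a 2-layer pyramid
  set.seed(58)
  g <- matrix(runif(64), 8, 8)
  ex2 <- pyramid_extractor(2)
  v2 <- layered_feature_corr(list(f, g), times, 2, ex2)
  pool2 <- function(m) {
    out <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4)
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  expect_equal(v2[1], cor(as.vector(f), as.vector(g)))
  expect_equal(v2[2], cor(as.vector(pool2(f)), as.vector(pool2(g))))
})

test_that("SVD compaction honors rank, variance targets and orthogonality", {
  set.seed(59)
  # rank 1: one component explains everything
  u <- rnorm(40); v <- rnorm(5)
  X1 <- outer(u, v) + 0 # rank 1
  s1 <- svd_compact(X1, variance_target = 0.9, center = FALSE, scale. = FALSE)
  expect_equal(attr(s1, "n_components"), 1L)
  expect_gt(attr(s1, "variance_explained")[1], 0.999)

  # equal-variance orthogonal columns: need ceil(0.9 m) components
  m <- 10
  Q <- qr.Q(qr(matrix(rnorm(200 * m), 200, m)))
  s2 <- svd_compact(Q, variance_target = 0.9, center = FALSE, scale. = FALSE)
  expect_equal(attr(s2, "n_components"), as.integer(ceiling(0.9 * m)))

  # duplicated column leaves the component count unchanged
  X <- matrix(rnorm(200), 40, 5)
  n1 <- attr(svd_compact(X, 0.9), "n_components")
  n2 <- attr(svd_compact(cbind(X, X[, 3]), 0.9), "n_components")
  expect_equal(n1, n2)

  # scores orthogonal
  s3 <- svd_compact(X, k = 3)
  cp <- crossprod(s3)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_error(svd_compact(cbind(X, 0)), "zero-variance")
})

test_that("shot flags follow the nearest shot transition within 1 TR", {
  shots <- data.frame(onset_s = c(0, 30, 60, 90),
                      location_id = c("a", "a", "b", "b"),
                      temporal_progression = c(0, 0, 1, 0))
  b <- data.frame(run_id = "run1", time = c(60.5, 45, 89.2),
                  n_observers = 5L)
  fl <- shot_flags(b, shots, tr = 2)
  expect_equal(fl$isLoc, c(1L, 0L, 0L))   # 60.5 -> shot at 60 (loc change)
  expect_equal(fl$isTemp, c(1L, 0L, 0L))  # same shot carries temp flag
  expect_equal(fl$isLocTemp, c(1L, 0L, 0L))
  expect_true(attr(fl, "combined"))

  shots2 <- shots; shots2$temporal_progression <- c(0, 1, 0, 0)
  b2 <- data.frame(run_id = "run1", time = c(30.2, 60.4), n_observers = 5L)
  fl2 <- shot_flags(b2, shots2, tr = 2)
  expect_equal(fl2$isLoc, c(0L, 1L))
  expect_equal(fl2$isTemp, c(1L, 0L))
  expect_false(attr(fl2, "combined"))
})
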