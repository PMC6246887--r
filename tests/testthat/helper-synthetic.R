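# Shared fixture builders and independent oracles. Everything is generated in
# code; no binary fixtures.

# trial-beta table with known variance components:
# beta = slope * salience_score + participant intercept + item intercept + noise
make_beta_table <- function(n_p = 50, n_b = 30, slope = 0.5,
                            sd_participant = 0.3, sd_item = 0.2,
                            sd_noise = 1) {
  sal <- rep_len(1:3, n_b)
  tab <- expand.grid(participant_id = sprintf("p%03d", seq_len(n_p)),
                     bidx = seq_len(n_b), KEEP.OUT.ATTRS = FALSE)
  tab$boundary_id <- sprintf("b%03d", tab$bidx)
  tab$salience_bin <- c("low", "med", "high")[sal[tab$bidx]]
  tab$n_observers <- sal[tab$bidx] * 4L + 2L
  bp <- rnorm(n_p, 0, sd_participant)
  bi <- rnorm(n_b, 0, sd_item)
  tab$beta <- slope * sal[tab$bidx] + bp[as.integer(factor(tab$participant_id))] +
    bi[tab$bidx] + rnorm(nrow(tab), 0, sd_noise)
  tab$bidx <- NULL
  tab
}

# dense quadratic-form oracle for the spatially weighted image measures:
# builds the full pixel-pair weight matrix G (optionally truncated to a
# square neighborhood) and evaluates <x, G y> directly
dense_g_matrix <- function(h, w, sigma = 1, radius = Inf) {
  pos <- expand.grid(y = seq_len(h), x = seq_len(w))
  d2 <- outer(pos$y, pos$y, `-`)^2 + outer(pos$x, pos$x, `-`)^2
  G <- exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  if (is.finite(radius)) {
    dy <- abs(outer(pos$y, pos$y, `-`)); dx <- abs(outer(pos$x, pos$x, `-`))
    G[dy > radius | dx > radius] <- 0
  }
  G
}

dense_imed <- function(a, b, sigma = 1, radius = Inf) {
  qform <- function(ma, mb) {
    G <- dense_g_matrix(nrow(ma), ncol(ma), sigma, radius)
    e <- as.vector(ma - mb)
    drop(t(e) %*% G %*% e)
  }
  if (length(dim(a)) == 3L) {
    sqrt(sum(vapply(seq_len(dim(a)[3]), function(c)
      qform(a[, , c], b[, , c]), numeric(1))))
  } else sqrt(qform(a, b))
}

dense_imncc <- function(a, b, sigma = 1, radius = Inf) {
  G <- dense_g_matrix(nrow(a), ncol(a), sigma, radius)
  x <- as.vector(a); y <- as.vector(b)
  drop(t(x) %*% G %*% y) /
    sqrt(drop(t(x) %*% G %*% x) * drop(t(y) %*% G %*% y))
}

# exhaustive oracle for the greedy event search: best RSS over all pairs of
# candidate TRs under the same positivity constraint
exhaustive_pair_rss <- function(y, tr, spec = hrf_spec()) {
  n <- length(y)
  template <- filmseg:::convolve_sticks(0, 1, n, tr, spec)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) C[j:n, j] <- template[seq_len(n - j + 1L)]
  best <- Inf; best_pair <- NULL
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    fit <- lm.fit(cbind(1, C[, c(i, j)]), y)
    if (any(is.na(fit$coefficients[-1])) || any(fit$coefficients[-1] <= 0)) next
    rss <- sum(fit$residuals^2)
    if (rss < best) { best <- rss; best_pair <- c(i, j) }
  }
  list(rss = best, pair = best_pair)
}

# flat observer log where every observer marks every boundary exactly
perfect_annotations <- function(times, n_observers = 8, rt = 0.9,
                                run_id = "run1") {
  observer_annotations(
    observer_id = rep(sprintf("o%02d", seq_len(n_observers)),
                      each = length(times)),
    run_id = run_id,
    press_time_s = rep(times + rt, n_observers))
}

# boundary table straight from an observer-count tally (counts named by value)
boundaries_from_tally <- function(tally, gap = 30) {
  n_obs <- rep(as.integer(names(tally)), tally)
  data.frame(run_id = "run1", time = seq_along(n_obs) * gap,
             n_observers = n_obs, salience_bin = NA_character_)
}
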