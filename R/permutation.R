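#' Permute boundary positions by shuffling event durations
#'
#' The event durations (run start to first boundary, then the intervals
#' between consecutive boundaries) are randomly permuted and cumulatively
#' summed; the tail after the last boundary is held fixed, so the number of
#' boundaries and the occupied span are preserved exactly. This is the null
#' used throughout: boundary count and inter-event interval distribution are
#' kept, positions are randomized.
#'
#' @param times numeric boundary times (>= 2 values, one run).
#' @param run_duration run duration in seconds (times must fit within it).
#' @param include_onset logical; if FALSE the first interval (run start to
#'   first boundary) is held fixed and only inter-boundary intervals are
#'   shuffled.
#' @return permuted boundary times (sorted ascending).
#' @export
shuffle_durations <- function(times, run_duration, include_onset = TRUE) {
  times <- sort(times)
  if (length(times) < 2L) stop("need at least 2 boundaries to shuffle durations")
  if (max(times) > run_duration) stop("boundaries exceed run_duration")
  if (include_onset) {
    iv <- diff(c(0, times))
    cumsum(sample(iv))
  } else {
    iv <- diff(times)
    times[1] + c(0, cumsum(sample(iv)))
  }
}

perm_result <- function(observed, null, p, n_perm, alternative) {
  structure(list(observed = observed, null = null, p = p,
                 n_perm = n_perm, alternative = alternative),
            class = "perm_result")
}

#' @export
#' @method print perm_result
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed = %.4g, p = %.4g (%s, %d permutations)\n",
              x$observed, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Permutation test of the boundary-evoked response amplitude
#'
#' The observed statistic is the single-predictor GLM amplitude of the
#' response to the boundaries ([estimate_amplitude()] with a `"single"`
#' scheme design). The null redistributes the boundaries by duration
#' shuffling and re-estimates; p is two-tailed with the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, so p is never 0. With
#' multiple runs, boundaries are shuffled within run and the statistic is a
#' single GLM across the concatenated runs, exactly as for the observed data.
#'
#' @param tcs an [roi_tc()] (single run) or named list of per-run
#'   [roi_tc()] objects.
#' @param boundaries consensus-boundary data frame or numeric times.
#' @param tr repetition time in seconds.
#' @param spec an [hrf_spec()].
#' @param n_perm number of permutations.
#' @param highpass_cutoff cosine-set cutoff in seconds.
#' @param include_onset passed to [shuffle_durations()].
#' @param seed optional integer seed.
#' @return a `perm_result`.
#' @export
amplitude_null <- function(tcs, boundaries, tr, spec = hrf_spec(),
                           n_perm = 1000, highpass_cutoff = 256,
                           include_onset = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(tcs, "roi_tc")) tcs <- stats::setNames(list(tcs), tcs$run_id)
  if (is.data.frame(boundaries)) {
    btimes <- split(boundaries$time, boundaries$run_id)
  } else {
    btimes <- stats::setNames(list(as.numeric(boundaries)), names(tcs)[1])
  }
  runs <- names(btimes)
  if (!all(runs %in% names(tcs))) stop("boundary runs missing from time courses")

  # residualize signal and event regressor against each run's confound set
  # (partitioned regression), then pool: one amplitude across runs, with
  # run-wise confounds, exactly as a block-diagonal GLM would give
  conf_qr <- lapply(runs, function(run) {
    tc <- tcs[[run]]
    qr(cbind(1, cosine_basis(length(tc$values), tr,
                             highpass_cutoff %||% Inf)))
  })
  names(conf_qr) <- runs
  ry <- lapply(runs, function(run) qr.resid(conf_qr[[run]], tcs[[run]]$values))
  names(ry) <- runs
  stat_for <- function(btimes) {
    num <- 0; den <- 0
    for (run in runs) {
      ev <- convolve_sticks(btimes[[run]], rep(1, length(btimes[[run]])),
                            length(tcs[[run]]$values), tr, spec)
      rev_ <- qr.resid(conf_qr[[run]], ev)
      num <- num + sum(rev_ * ry[[run]])
      den <- den + sum(rev_^2)
    }
    num / den
  }

  observed <- stat_for(btimes)
  null <- numeric(n_perm)
  durs <- vapply(runs, function(run) length(tcs[[run]]$values) * tr, numeric(1))
  for (i in seq_len(n_perm)) {
    bi <- lapply(runs, function(run)
      shuffle_durations(btimes[[run]], durs[[run]], include_onset))
    names(bi) <- runs
    null[i] <- stat_for(bi)
  }
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  perm_result(observed, null, p, n_perm, "two-tailed")
}

#' Permutation test of a boundary match count
#'
#' Counts one-to-one matches (within `window` seconds) between a test event
#' set and a reference set, then compares the count with the match obtained
#' against duration-shuffled reference events. One-tailed (greater), add-one
#' p estimator.
#'
#' @param reference_events numeric reference times (the set that is
#'   shuffled).
#' @param test_events numeric test times.
#' @param window matching window in seconds.
#' @param run_duration run duration in seconds.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return a `perm_result` with the observed match count.
#' @export
match_null <- function(reference_events, test_events, window, run_duration,
                       n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observed <- nrow(greedy_match(reference_events, test_events, window))
  if (length(test_events) == 0L || length(reference_events) < 2L)
    return(perm_result(observed, rep(0L, n_perm), 1, n_perm, "greater"))
  null <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ref_i <- shuffle_durations(reference_events, run_duration)
    null[i] <- nrow(greedy_match(ref_i, test_events, window))
  }
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  perm_result(observed, null, p, n_perm, "greater")
}
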