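#' Greedy data-driven detection of ROI events
#'
#' Starting from a constant-only model of the (high-pass filtered, z-scored,
#' group-averaged) ROI time course, iteratively adds the HRF-convolved stick
#' predictor — one candidate per TR — whose inclusion most reduces the
#' residual sum of squares, refitting all coefficients jointly at each step,
#' under two constraints: the new event's coefficient must be positive and
#' no previously selected event coefficient may change sign. Stops after `k`
#' events or when no admissible candidate remains (`stopped_early`). Ties in
#' RSS reduction are broken toward the earlier TR.
#'
#' @param tc an [roi_tc()] (one run).
#' @param k target number of events (>= 1, <= number of TRs).
#' @param spec an [hrf_spec()].
#' @return object of class `roi_event_set`: `event_trs` (in selection
#'   order), `event_times` (seconds), `betas` (joint fit, selection order),
#'   `rss_trace` (RSS after each selection, preceded by the constant-only
#'   RSS), `fitted`, `stopped_early`.
#' @export
greedy_event_search <- function(tc, k, spec = hrf_spec()) {
  stopifnot(inherits(tc, "roi_tc"))
  y <- tc$values; n <- length(y); tr <- tc$tr
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (k > n) stop("'k' exceeds the number of TRs")

  # candidate regressors: stick at the onset of each TR, convolved; a stick
  # on the TR grid is shift-invariant at microtime resolution, so shift one
  # template instead of convolving n times
  template <- convolve_sticks(0, 1, n, tr, spec)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- n - j + 1L
    C[j:n, j] <- template[seq_len(len)]
  }

  selected <- integer(0)
  const_fit <- stats::lm.fit(matrix(1, n, 1), y)
  rss_trace <- sum(const_fit$residuals^2)
  betas <- numeric(0)
  fitted <- const_fit$fitted.values
  stopped_early <- FALSE

  while (length(selected) < k) {
    candidates <- setdiff(seq_len(n), selected)
    cur_rss <- utils::tail(rss_trace, 1)
    best <- NULL
    for (j in candidates) {
      X <- cbind(1, C[, c(selected, j), drop = FALSE])
      fit <- stats::lm.fit(X, y)
      co <- fit$coefficients[-1]
      if (anyNA(co)) next
      if (co[length(co)] <= 0) next
      if (length(selected) && any(sign(co[seq_along(selected)]) != sign(betas)))
        next
      rss <- sum(fit$residuals^2)
      # must actually reduce the residual error (keeps the trace strictly
      # decreasing; a candidate with nothing left to explain is inadmissible)
      if (rss >= cur_rss - 1e-10 * max(1, cur_rss)) next
      if (is.null(best) || rss < best$rss - 1e-12 ||
          (abs(rss - best$rss) <= 1e-12 && j < best$j)) {
        best <- list(j = j, rss = rss, co = co, fitted = fit$fitted.values)
      }
    }
    if (is.null(best)) { stopped_early <- TRUE; break }
    selected <- c(selected, best$j)
    betas <- best$co
    rss_trace <- c(rss_trace, best$rss)
    fitted <- best$fitted
  }

  structure(list(event_trs = selected,
                 event_times = (selected - 1) * tr,
                 betas = betas,
                 rss_trace = rss_trace,
                 fitted = fitted,
                 k_target = k,
                 stopped_early = stopped_early,
                 tr = tr),
            class = "roi_event_set")
}

#' @export
#' @method print roi_event_set
print.roi_event_set <- function(x, ...) {
  cat(sprintf("<roi_event_set> %d/%d events%s; RSS %.4g -> %.4g\n",
              length(x$event_trs), x$k_target,
              if (x$stopped_early) " (stopped early)" else "",
              x$rss_trace[1], utils::tail(x$rss_trace, 1)))
  invisible(x)
}

#' Specificity of data-driven events to consensus boundaries
#'
#' Matches the detected events one-to-one to the boundaries (within
#' `window_tr` TRs) and assesses the match count against duration-shuffled
#' boundaries via [match_null()].
#'
#' @param events an `roi_event_set` from [greedy_event_search()].
#' @param boundaries numeric boundary times (seconds) or a
#'   consensus-boundary data frame (single run).
#' @param run_duration run duration in seconds.
#' @param window_tr matching window in TRs (default 1).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `matches`, `fraction` (of detected events), `matched`
#'   (logical per event), and the `perm` result.
#' @export
specificity_test <- function(events, boundaries, run_duration,
                             window_tr = 1, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(events, "roi_event_set"))
  btimes <- if (is.data.frame(boundaries)) boundaries$time else as.numeric(boundaries)
  window <- window_tr * events$tr
  m <- greedy_match(btimes, events$event_times, window)
  matched <- logical(length(events$event_times))
  matched[m$test_idx] <- TRUE
  perm <- match_null(btimes, events$event_times, window, run_duration,
                     n_perm = n_perm, seed = seed)
  list(matches = nrow(m),
       fraction = if (length(matched)) mean(matched) else NA_real_,
       matched = matched, perm = perm)
}
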