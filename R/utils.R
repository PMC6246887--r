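#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova approx as.formula complete.cases convolve cor
#'   dgamma fft lm.fit model.matrix p.adjust quantile rbinom reformulate
#'   rnorm rpois runif sd setNames var
#' @importFrom utils head read.delim tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Greedy one-to-one matching between two sets of event times
#'
#' Pairs each test event with at most one reference event (and vice versa),
#' assigning pairs in order of ascending temporal distance. With
#' `asymmetric = TRUE` a pair is eligible only when the reference event
#' precedes (or coincides with) the test event by at most `window` seconds;
#' otherwise any pair within `window` in absolute value is eligible.
#'
#' @param t_ref numeric vector of reference event times (seconds).
#' @param t_test numeric vector of test event times (seconds).
#' @param window matching window in seconds.
#' @param asymmetric logical; if TRUE, require `0 <= t_test - t_ref <= window`.
#' @return data frame with columns `ref_idx`, `test_idx`, `dt`
#'   (test minus reference), one row per matched pair.
#' @export
greedy_match <- function(t_ref, t_test, window, asymmetric = FALSE) {
  empty <- data.frame(ref_idx = integer(), test_idx = integer(), dt = numeric())
  if (length(t_ref) == 0L || length(t_test) == 0L) return(empty)
  dt <- outer(t_test, t_ref, `-`) # test x ref
  ok <- if (asymmetric) dt >= 0 & dt <= window else abs(dt) <= window
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  d <- abs(dt[idx])
  ord <- order(d, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  used_t <- logical(length(t_test)); used_r <- logical(length(t_ref))
  out <- vector("list", nrow(idx)); n <- 0L
  for (i in seq_len(nrow(idx))) {
    ti <- idx[i, 1L]; ri <- idx[i, 2L]
    if (used_t[ti] || used_r[ri]) next
    used_t[ti] <- TRUE; used_r[ri] <- TRUE
    n <- n + 1L
    out[[n]] <- data.frame(ref_idx = ri, test_idx = ti,
                           dt = t_test[ti] - t_ref[ri])
  }
  if (n == 0L) return(empty)
  do.call(rbind, out[seq_len(n)])
}

# z-score a numeric vector; errors on zero variance (NaN propagation is never
# the right answer for a BOLD time course)
zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant (zero-variance) series")
  (x - mean(x)) / s
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
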