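#' Ordered-event hidden Markov segmentation of multi-voxel patterns
#'
#' Fits a left-to-right HMM with `k_events` states to a voxel x TR pattern
#' matrix: each state (event) has a Gaussian mean pattern with shared
#' isotropic variance; the state sequence starts in event 1, can only stay
#' or advance by one at each TR, and must end in event K. Means and variance
#' are estimated by EM (forward-backward E-step with the start/end
#' constraints); the stay probability is fixed from the expected event
#' length, `1 - (K - 1) / (T - 1)` advances expected per TR. Pattern-shift
#' times are taken from the constrained Viterbi path, so there are always
#' exactly K - 1 shifts.
#'
#' @param patterns voxel x TR numeric matrix; z-scored per voxel internally
#'   (constant voxels are dropped with a warning).
#' @param k_events number of events K (1 <= K <= number of TRs).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `hmm_fit`: `n_events`, `state_posterior`
#'   (TR x K), `event_means` (voxel x K), `shift_times` (TR indices at which
#'   the modal state increments), `loglik_trace`, `converged`.
#' @export
fit_event_hmm <- function(patterns, k_events, max_iter = 100, tol = 1e-4) {
  M <- as.matrix(patterns)
  K <- as.integer(k_events)
  T_ <- ncol(M)
  if (K < 1L || K > T_) stop("k_events must be in 1..n_TR")
  keep <- apply(M, 1, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant voxel(s) before z-scoring")
    M <- M[keep, , drop = FALSE]
  }
  M <- t(apply(M, 1, zscore_vec))
  X <- t(M) # TR x voxel
  V <- ncol(X)

  if (K == 1L) {
    post <- matrix(1, T_, 1)
    return(structure(list(n_events = 1L, state_posterior = post,
                          event_means = matrix(colMeans(X), ncol = 1),
                          shift_times = integer(0),
                          loglik_trace = numeric(0), converged = TRUE),
                     class = "hmm_fit"))
  }

  # initialization: uniform spread of event lengths
  init_state <- pmin(K, floor((seq_len(T_) - 1L) * K / T_) + 1L)
  mu <- sapply(seq_len(K), function(k)
    colMeans(X[init_state == k, , drop = FALSE]))
  mu <- matrix(mu, nrow = V)
  sigma2 <- max(mean((X - t(mu[, init_state]))^2), 1e-8)
  p_stay <- if (T_ > 1L) max(1e-6, 1 - (K - 1) / (T_ - 1)) else 0.5
  l_stay <- log(p_stay); l_adv <- log1p(-p_stay)

  emission_ll <- function(mu, sigma2) {
    # TR x K matrix of log N(x_t; mu_k, sigma2 I)
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% mu +
      outer(rep(1, T_), colSums(mu^2))
    -d2 / (2 * sigma2) - V / 2 * log(2 * pi * sigma2)
  }

  ll_trace <- numeric(0)
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    lb <- emission_ll(mu, sigma2)
    # forward, constrained to start in state 1
    la <- matrix(-Inf, T_, K)
    la[1, 1] <- lb[1, 1]
    for (t in 2:T_) {
      prev <- la[t - 1, ]
      stay <- prev + l_stay
      adv <- c(-Inf, prev[-K] + l_adv)
      m <- pmax(stay, adv) # pairwise logsumexp

      la[t, ] <- lb[t, ] + ifelse(is.finite(m),
                                  m + log(exp(stay - m) + exp(adv - m)), -Inf)
    }
    # backward, constrained to end in state K
    lbw <- matrix(-Inf, T_, K)
    lbw[T_, K] <- 0
    for (t in (T_ - 1L):1L) {
      stay <- l_stay + lb[t + 1, ] + lbw[t + 1, ]
      adv <- c(l_adv + lb[t + 1, -1] + lbw[t + 1, -1], -Inf)
      m <- pmax(stay, adv)
      lbw[t, ] <- ifelse(is.finite(m),
                         m + log(exp(stay - m) + exp(adv - m)), -Inf)
    }
    ll <- la[T_, K]
    lg <- la + lbw - ll
    gamma <- exp(lg)
    gamma <- gamma / rowSums(gamma)

    # M-step: means and shared isotropic variance
    wk <- colSums(gamma)
    mu <- t(crossprod(gamma, X) / wk)
    resid2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% mu +
      outer(rep(1, T_), colSums(mu^2))
    sigma2 <- max(sum(gamma * resid2) / (T_ * V), 1e-8)

    ll_trace <- c(ll_trace, ll)
    if (iter > 1 &&
        abs(ll - ll_trace[iter - 1]) <=
          tol * (abs(ll_trace[iter - 1]) + 1e-12)) break
  }
  converged <- iter < max_iter ||
    (length(ll_trace) > 1 &&
       abs(diff(utils::tail(ll_trace, 2))) <=
         tol * (abs(ll_trace[length(ll_trace) - 1]) + 1e-12))
  if (!converged) warning("EM did not converge; returning best fit")

  # constrained Viterbi for the modal path (start 1, end K)
  lb <- emission_ll(mu, sigma2)
  delta <- matrix(-Inf, T_, K); psi <- matrix(1L, T_, K)
  delta[1, 1] <- lb[1, 1]
  for (t in 2:T_) {
    stay <- delta[t - 1, ] + l_stay
    adv <- c(-Inf, delta[t - 1, -K] + l_adv)
    take_adv <- adv > stay
    delta[t, ] <- lb[t, ] + pmax(stay, adv)
    psi[t, ] <- ifelse(take_adv, seq_len(K) - 1L, seq_len(K))
  }
  path <- integer(T_); path[T_] <- K
  for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  shifts <- which(diff(path) == 1L) + 1L

  structure(list(n_events = K, state_posterior = gamma, event_means = mu,
                 shift_times = shifts, viterbi_path = path,
                 loglik_trace = ll_trace, sigma2 = sigma2,
                 converged = converged),
            class = "hmm_fit")
}

#' @export
#' @method print hmm_fit
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d events, %d TRs, %d EM iterations%s\n",
              x$n_events, nrow(x$state_posterior), length(x$loglik_trace),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Classify pattern shifts as matching an event boundary or not
#'
#' A shift matches when a boundary occurred up to `window_tr` TRs before it
#' (boundary precedes shift); assignment is greedy one-to-one by temporal
#' distance. Set `symmetric = TRUE` for a two-sided window.
#'
#' @param shift_trs TR indices of pattern shifts (first TR of the new
#'   event).
#' @param boundaries numeric boundary times in seconds, or a
#'   consensus-boundary data frame.
#' @param tr repetition time in seconds.
#' @param window_tr matching window in TRs (default 2).
#' @param symmetric use a symmetric window instead of boundary-before-shift.
#' @return data frame: `shift_tr`, `shift_time`, `matched`, `boundary_time`.
#' @export
classify_shifts <- function(shift_trs, boundaries, tr, window_tr = 2,
                            symmetric = FALSE) {
  btimes <- if (is.data.frame(boundaries)) boundaries$time else as.numeric(boundaries)
  shift_times <- (shift_trs - 1) * tr
  m <- greedy_match(btimes, shift_times, window = window_tr * tr,
                    asymmetric = !symmetric)
  out <- data.frame(shift_tr = shift_trs, shift_time = shift_times,
                    matched = FALSE, boundary_time = NA_real_)
  if (nrow(m)) {
    out$matched[m$test_idx] <- TRUE
    out$boundary_time[m$test_idx] <- btimes[m$ref_idx]
  }
  out
}

#' Peri-shift averaged ROI response
#'
#' Extracts epochs of the (group-averaged, z-scored) ROI time course around
#' each pattern shift, averages them within match / non-match class, and
#' summarizes the response amplitude as the mean over TRs 0..2 relative to
#' the shift. Significance per class is assessed by duration-shuffling the
#' shift times (epochs between shifts) and recomputing the amplitude.
#'
#' @param tc an [roi_tc()] (typically from [zscore_and_average()]).
#' @param shifts data frame from [classify_shifts()].
#' @param pre_tr,post_tr epoch extent in TRs before/after the shift.
#' @param amp_window TR offsets (relative to the shift) averaged for the
#'   amplitude (default 0:2, a 3-sample inclusive mean).
#' @param n_perm permutations for the amplitude null (0 skips it).
#' @param seed optional integer seed.
#' @return list with `lags` (TR offsets), per-class `curves` and
#'   `amplitude`, epoch counts, and per-class permutation `p` when
#'   `n_perm > 0`.
#' @export
peri_shift_response <- function(tc, shifts, pre_tr = 2, post_tr = 6,
                                amp_window = 0:2, n_perm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- tc$values; n <- length(y)
  lags <- seq(-pre_tr, post_tr)
  epoch_of <- function(tr_idx) {
    idx <- tr_idx + lags
    v <- rep(NA_real_, length(lags))
    ok <- idx >= 1L & idx <= n
    v[ok] <- y[idx[ok]]
    v
  }
  amp_of <- function(tr_idx) {
    idx <- tr_idx + amp_window
    mean(y[idx[idx >= 1L & idx <= n]])
  }
  classes <- list(match = shifts$shift_tr[shifts$matched],
                  nonmatch = shifts$shift_tr[!shifts$matched])
  curves <- list(); amps <- list(); pvals <- list()
  for (cl in names(classes)) {
    trs <- classes[[cl]]
    if (!length(trs)) {
      curves[[cl]] <- rep(NA_real_, length(lags)); amps[[cl]] <- NA_real_
      next
    }
    ep <- t(vapply(trs, epoch_of, numeric(length(lags))))
    curves[[cl]] <- colMeans(ep, na.rm = TRUE)
    amps[[cl]] <- mean(vapply(trs, amp_of, numeric(1)))
    if (n_perm > 0 && length(shifts$shift_tr) >= 2L) {
      obs <- amps[[cl]]
      null <- numeric(n_perm)
      all_times <- sort((shifts$shift_tr - 1) * tc$tr)
      n_cl <- length(trs)
      for (i in seq_len(n_perm)) {
        perm_times <- shuffle_durations(all_times, n * tc$tr)
        perm_trs <- pmin(pmax(round(perm_times / tc$tr) + 1L, 1L), n)
        sel <- sample(perm_trs, n_cl)
        null[i] <- mean(vapply(sel, amp_of, numeric(1)))
      }
      pvals[[cl]] <- (1 + sum(null >= obs)) / (n_perm + 1)
    }
  }
  list(lags = lags, curves = curves, amplitude = amps,
       n_epochs = vapply(classes, length, integer(1)),
       p = if (length(pvals)) pvals else NULL)
}
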