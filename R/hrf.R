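#' Specification of the canonical double-gamma hemodynamic response
#'
#' The canonical HRF is the difference of two gamma densities: a positive
#' response peaking about 5 s after the event and a later undershoot. Delays
#' are the gamma shape parameters times their dispersions, so with the default
#' `peak_delay = 6`, `peak_dispersion = 1` the kernel mode falls at 5 s.
#' `undershoot_ratio` is the relative amplitude of the undershoot (0 gives a
#' pure positive gamma with no negative lobe).
#'
#' @param peak_delay,peak_dispersion seconds; gamma parameters of the response.
#' @param undershoot_delay,undershoot_dispersion seconds; gamma parameters of
#'   the undershoot.
#' @param undershoot_ratio unitless relative undershoot amplitude (>= 0).
#' @param kernel_length seconds of kernel support (>= 24).
#' @param microtime_bins number of microtime bins per TR used when placing
#'   stick functions at real-valued event times.
#' @return an object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6,
                     kernel_length = 32, microtime_bins = 16L) {
  stopifnot_scalar(peak_delay, "peak_delay", positive = TRUE)
  stopifnot_scalar(undershoot_delay, "undershoot_delay", positive = TRUE)
  stopifnot_scalar(peak_dispersion, "peak_dispersion", positive = TRUE)
  stopifnot_scalar(undershoot_dispersion, "undershoot_dispersion", positive = TRUE)
  stopifnot_scalar(undershoot_ratio, "undershoot_ratio", nonneg = TRUE)
  stopifnot_scalar(kernel_length, "kernel_length", positive = TRUE)
  if (kernel_length < 24) stop("'kernel_length' must be at least 24 s")
  microtime_bins <- as.integer(microtime_bins)
  if (microtime_bins < 1L) stop("'microtime_bins' must be >= 1")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length,
                 microtime_bins = microtime_bins),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel at microtime resolution
#'
#' @param spec an [hrf_spec()].
#' @param tr repetition time in seconds.
#' @return list with `kernel` (values, unit peak) and `times` (seconds),
#'   sampled every `tr / microtime_bins` seconds.
#' @export
canonical_hrf <- function(spec = hrf_spec(), tr) {
  stopifnot(inherits(spec, "hrf_spec"))
  stopifnot_scalar(tr, "tr", positive = TRUE)
  dt <- tr / spec$microtime_bins
  t <- seq(0, spec$kernel_length, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                    scale = spec$undershoot_dispersion)
  h <- h / max(h)
  list(kernel = h, times = t, dt = dt)
}

#' Discrete cosine high-pass basis (drift confounds)
#'
#' The standard cosine set used to implement high-pass filtering within the
#' GLM: `floor(2 * n_tr * tr / cutoff)` cosines spanning periods longer than
#' the cutoff (default 256 s).
#'
#' @param n_tr number of time points.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds.
#' @return matrix with `n_tr` rows (possibly zero columns), columns named
#'   `cos1`, `cos2`, ...
#' @export
cosine_basis <- function(n_tr, tr, cutoff = 256) {
  n_tr <- as.integer(n_tr)
  k_max <- floor(2 * n_tr * tr / cutoff)
  t <- seq_len(n_tr) - 1L
  if (k_max < 1L)
    return(matrix(numeric(0), nrow = n_tr, ncol = 0L))
  C <- sapply(seq_len(k_max), function(k)
    sqrt(2 / n_tr) * cos(pi * (2 * t + 1) * k / (2 * n_tr)))
  C <- matrix(C, nrow = n_tr)
  colnames(C) <- paste0("cos", seq_len(k_max))
  C
}

# convolve microtime impulses with the HRF kernel and sample at the middle
# microtime bin of each TR (matching slice-time correction to the middle slice)
convolve_sticks <- function(times, weights, n_tr, tr, spec) {
  hk <- canonical_hrf(spec, tr)
  nb <- spec$microtime_bins
  n_micro <- n_tr * nb
  u <- numeric(n_micro)
  if (length(times)) {
    bins <- floor(times / hk$dt) + 1L
    if (any(bins < 1L | bins > n_micro))
      stop("event time outside the sampled run")
    for (i in seq_along(bins)) u[bins[i]] <- u[bins[i]] + weights[i]
  }
  conv <- stats::convolve(u, rev(hk$kernel), type = "open")[seq_len(n_micro)]
  sample_bin <- max(1L, nb %/% 2L)
  conv[(seq_len(n_tr) - 1L) * nb + sample_bin]
}

#' Build a GLM design matrix for boundary-evoked responses
#'
#' Places unit stick functions at real-valued boundary times on a microtime
#' grid, convolves them with the canonical HRF and samples the result at the
#' middle of each TR. A cosine high-pass confound set (plus a constant) is
#' appended. Three schemes are supported: a `"single"` column for all
#' boundaries, one column `"per-boundary"`, or a condition-by-lag `"fir"`
#' basis on a 1 s grid (for use with 1 s-interpolated time courses).
#'
#' @param boundaries numeric vector of boundary times (seconds) or a
#'   consensus-boundary data frame with a `time` column.
#' @param n_tr number of time points of the run (TRs, or seconds for
#'   `scheme = "fir"`).
#' @param tr repetition time in seconds (1 for the FIR grid).
#' @param spec an [hrf_spec()].
#' @param scheme design scheme; see Details.
#' @param highpass_cutoff cosine-set cutoff in seconds; `NULL` drops the set.
#' @param conditions for `scheme = "fir"`, a factor of per-boundary condition
#'   labels (e.g. salience bins).
#' @param fir_range two-element numeric, peri-event window in seconds.
#' @return an object of class `design_matrix`: list with the design `X`,
#'   `event_cols`, `confound_cols`, and a `full_rank` flag.
#' @export
build_design <- function(boundaries, n_tr, tr, spec = hrf_spec(),
                         scheme = c("single", "per-boundary", "fir"),
                         highpass_cutoff = 256,
                         conditions = NULL, fir_range = c(-2, 12)) {
  scheme <- match.arg(scheme)
  times <- if (is.data.frame(boundaries)) boundaries$time else as.numeric(boundaries)
  n_tr <- as.integer(n_tr)
  if (length(times) && any(times < 0)) stop("boundary times must be >= 0")
  if (length(times) && max(times) > n_tr * tr)
    stop("boundary time beyond the end of the run")
  truncated <- length(times) > 0 &&
    (max(times) + spec$kernel_length > n_tr * tr)

  if (scheme == "fir") {
    if (is.null(conditions)) conditions <- factor(rep("all", length(times)))
    conditions <- droplevels(as.factor(conditions))
    lags <- seq(fir_range[1], fir_range[2])
    cols <- list()
    for (cond in levels(conditions)) {
      ts <- times[conditions == cond]
      for (l in lags) {
        v <- numeric(n_tr)
        idx <- round(ts) + l + 1L # 1 s grid, origin t = 0
        idx <- idx[idx >= 1L & idx <= n_tr]
        v[idx] <- 1
        cols[[sprintf("%s_lag%+d", cond, l)]] <- v
      }
    }
    Xe <- do.call(cbind, cols)
  } else if (scheme == "single") {
    if (length(times) == 0L) {
      Xe <- matrix(numeric(0), nrow = n_tr, ncol = 0L)
    } else {
      Xe <- matrix(convolve_sticks(times, rep(1, length(times)), n_tr, tr, spec),
                   ncol = 1L)
      colnames(Xe) <- "events"
    }
  } else { # per-boundary
    dt <- tr / spec$microtime_bins
    bins <- floor(times / dt)
    if (anyDuplicated(bins))
      stop("two boundaries fall in the same microtime bin; per-boundary design is unresolvable")
    Xe <- sapply(times, function(b) convolve_sticks(b, 1, n_tr, tr, spec))
    Xe <- matrix(Xe, nrow = n_tr)
    if (ncol(Xe)) colnames(Xe) <- sprintf("b%03d", seq_along(times))
  }

  conf <- cbind(const = rep(1, n_tr),
                if (!is.null(highpass_cutoff)) cosine_basis(n_tr, tr, highpass_cutoff))
  X <- cbind(Xe, conf)
  qx <- qr(X)
  structure(list(X = X,
                 event_cols = colnames(Xe) %||% character(),
                 confound_cols = colnames(conf),
                 n_tr = n_tr, tr = tr, scheme = scheme,
                 boundary_times = times,
                 full_rank = qx$rank == ncol(X),
                 truncated = truncated),
            class = "design_matrix")
}

#' Ordinary least-squares amplitude estimation
#'
#' Fits the time course against a [build_design()] matrix and returns the
#' event-column coefficients (the boundary-response amplitudes), the residual
#' series and the residual sum of squares.
#'
#' @param tc an [roi_tc()] object or numeric vector.
#' @param design a `design_matrix`.
#' @return list with `beta` (named event amplitudes), `coef` (all
#'   coefficients), `residuals`, `fitted` and `rss`.
#' @export
estimate_amplitude <- function(tc, design) {
  stopifnot(inherits(design, "design_matrix"))
  y <- if (inherits(tc, "roi_tc")) tc$values else as.numeric(tc)
  X <- design$X
  if (length(y) != nrow(X))
    stop("time course length does not match design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  list(beta = co[design$event_cols],
       coef = co,
       residuals = fit$residuals,
       fitted = fit$fitted.values,
       rss = sum(fit$residuals^2))
}

#' Remove boundaries too close for single-trial estimation
#'
#' Both members of any pair of boundaries closer than `min_gap` seconds are
#' removed, since their responses cannot be dissociated in a single-trial GLM.
#'
#' @param times numeric boundary times (one run).
#' @param min_gap minimum separation in seconds (default 6).
#' @return logical vector, TRUE for retained boundaries.
#' @export
boundary_gap_keep <- function(times, min_gap = 6) {
  if (length(times) < 2L) return(rep(TRUE, length(times)))
  o <- order(times)
  ts <- times[o]
  close_prev <- c(FALSE, diff(ts) < min_gap)
  close_next <- c(diff(ts) < min_gap, FALSE)
  keep_sorted <- !(close_prev | close_next)
  keep <- logical(length(times))
  keep[o] <- keep_sorted
  keep
}

#' Single-trial boundary amplitudes for every participant
#'
#' For each participant (and run) fits one GLM containing a separate
#' HRF-convolved stick predictor for every retained boundary (least-squares-
#' all), after removing both members of any boundary pair closer than
#' `min_gap` seconds.
#'
#' @param tcs either a list of [roi_tc()] objects (one per participant,
#'   single run) or a list of participants each holding a named list of
#'   per-run [roi_tc()] objects.
#' @param boundaries consensus-boundary data frame (`run_id`, `time`,
#'   `n_observers`, optionally `salience_bin`).
#' @param tr repetition time in seconds.
#' @param spec an [hrf_spec()].
#' @param min_gap minimum boundary separation in seconds.
#' @param highpass_cutoff cosine-set cutoff in seconds.
#' @return a long-format data frame (the trial-beta table): one row per
#'   participant x retained boundary with columns `participant_id`, `run_id`,
#'   `boundary_id`, `time`, `n_observers`, `salience_bin`, `beta`.
#' @export
single_trial_betas <- function(tcs, boundaries, tr, spec = hrf_spec(),
                               min_gap = 6, highpass_cutoff = 256) {
  stopifnot(is.data.frame(boundaries), "time" %in% names(boundaries))
  if (is.null(boundaries$run_id)) boundaries$run_id <- "run1"
  # normalize tcs to participant -> run -> tc
  if (all(vapply(tcs, inherits, TRUE, what = "roi_tc"))) {
    tcs <- lapply(tcs, function(tc) stats::setNames(list(tc), tc$run_id))
  }
  if (is.null(names(tcs)))
    names(tcs) <- sprintf("p%03d", seq_along(tcs))

  out <- list()
  for (run in unique(boundaries$run_id)) {
    b <- boundaries[boundaries$run_id == run, , drop = FALSE]
    b <- b[order(b$time), , drop = FALSE]
    keep <- boundary_gap_keep(b$time, min_gap)
    b <- b[keep, , drop = FALSE]
    if (nrow(b) == 0L) next
    for (p in names(tcs)) {
      tc <- tcs[[p]][[run]]
      if (is.null(tc)) next
      des <- build_design(b$time, length(tc$values), tr, spec,
                          scheme = "per-boundary",
                          highpass_cutoff = highpass_cutoff)
      est <- estimate_amplitude(tc, des)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = p, run_id = run,
        boundary_id = sprintf("%s@%.3f", run, b$time),
        time = b$time,
        n_observers = b$n_observers %||% rep(NA_integer_, nrow(b)),
        salience_bin = as.character(b$salience_bin %||% rep(NA_character_, nrow(b))),
        beta = unname(est$beta))
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(), run_id = character(),
                      boundary_id = character(), time = numeric(),
                      n_observers = integer(), salience_bin = character(),
                      beta = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' FIR (finite impulse response) peri-boundary time courses
#'
#' Estimates the unconstrained response at each 1 s lag in `fir_range` around
#' the boundaries, per condition (salience bin), for each participant, after
#' linearly interpolating each time course to a 1 s grid. Returns the
#' across-participant mean and SEM per condition and lag.
#'
#' @param tcs list of [roi_tc()] objects, one per participant (single run).
#' @param boundaries consensus-boundary data frame with `time` and
#'   `salience_bin` (if absent, a single condition is used).
#' @param tr repetition time of the input series in seconds.
#' @param fir_range peri-event window in seconds.
#' @return list with `lags`, `conditions`, matrices `mean` and `sem`
#'   (condition x lag) and the per-participant array `betas`.
#' @export
fir_timecourse <- function(tcs, boundaries, tr, fir_range = c(-2, 12)) {
  times <- boundaries$time
  conds <- boundaries$salience_bin %||% rep("all", length(times))
  conds <- droplevels(as.factor(conds))
  lags <- seq(fir_range[1], fir_range[2])
  n_sec <- floor(length(tcs[[1]]$values) * tr)
  des <- build_design(times, n_sec, 1, scheme = "fir",
                      highpass_cutoff = NULL, conditions = conds,
                      fir_range = fir_range)
  grid <- seq_len(n_sec) - 0.5 # second midpoints
  tr_times <- (seq_along(tcs[[1]]$values) - 0.5) * tr
  betas <- array(NA_real_,
                 dim = c(length(tcs), nlevels(conds), length(lags)),
                 dimnames = list(NULL, levels(conds), paste0("lag", lags)))
  for (i in seq_along(tcs)) {
    y <- stats::approx(tr_times, tcs[[i]]$values, xout = grid, rule = 2)$y
    est <- estimate_amplitude(y, des)
    for (cond in levels(conds)) {
      cn <- sprintf("%s_lag%+d", cond, lags)
      betas[i, cond, ] <- est$beta[cn]
    }
  }
  mu <- apply(betas, c(2, 3), mean)
  se <- apply(betas, c(2, 3), function(x) stats::sd(x) / sqrt(length(x)))
  list(lags = lags, conditions = levels(conds), mean = mu, sem = se,
       betas = betas)
}
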