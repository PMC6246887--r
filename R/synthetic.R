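#' Ground truth for synthetic film-viewing data
#'
#' Defines the latent structure that every simulated input shares: true
#' boundary times, the probability that any one observer detects each
#' boundary (its "salience"), and the BOLD response amplitude at each
#' boundary.
#'
#' @param boundary_times numeric vector of strictly increasing boundary
#'   times in seconds (one run), or a named list of such vectors (one per
#'   run).
#' @param run_length run length in seconds (scalar, recycled across runs).
#' @param tr repetition time in seconds.
#' @param salience_prob per-boundary detection probability in (0, 1]
#'   (scalar recycled, or shaped like `boundary_times`).
#' @param amplitudes per-boundary BOLD amplitude (scalar recycled, or shaped
#'   like `boundary_times`).
#' @param n_participants,n_observers simulated cohort sizes.
#' @return object of class `ground_truth`; boundary fields are stored as
#'   named per-run lists.
#' @export
ground_truth <- function(boundary_times, run_length, tr = 2,
                         salience_prob = 1, amplitudes = 1,
                         n_participants = 20L, n_observers = 16L) {
  if (!is.list(boundary_times)) boundary_times <- list(run1 = boundary_times)
  if (is.null(names(boundary_times)))
    names(boundary_times) <- sprintf("run%d", seq_along(boundary_times))
  runs <- names(boundary_times)
  run_length <- stats::setNames(rep_len(run_length, length(runs)), runs)
  shape_like <- function(x, what) {
    if (!is.list(x)) x <- lapply(boundary_times, function(b) rep_len(x, length(b)))
    x <- stats::setNames(x, runs)
    for (r in runs)
      if (length(x[[r]]) != length(boundary_times[[r]]))
        stop(sprintf("'%s' does not match boundary_times in run %s", what, r))
    x
  }
  salience_prob <- shape_like(salience_prob, "salience_prob")
  amplitudes <- shape_like(amplitudes, "amplitudes")
  stopifnot_scalar(tr, "tr", positive = TRUE)
  for (r in runs) {
    b <- boundary_times[[r]]
    if (is.unsorted(b, strictly = TRUE))
      stop("boundary_times must be strictly increasing")
    if (length(b) && (min(b) < 0 || max(b) >= run_length[[r]]))
      stop("boundary_times must lie within [0, run_length)")
    if (any(salience_prob[[r]] < 0 | salience_prob[[r]] > 1))
      stop("salience_prob must be in [0, 1]")
  }
  structure(list(boundary_times = boundary_times, run_length = run_length,
                 tr = tr, salience_prob = salience_prob,
                 amplitudes = amplitudes,
                 n_participants = as.integer(n_participants),
                 n_observers = as.integer(n_observers)),
            class = "ground_truth")
}

#' Simulate observer keypress logs
#'
#' Each observer independently detects each true boundary with its
#' `salience_prob`; a detected boundary produces a keypress at the boundary
#' time plus a reaction time (`rt_mean` + Gaussian jitter). Accidental
#' presses are added as a homogeneous Poisson process at `spurious_rate`
#' presses per second (default 0).
#'
#' @param gt a [ground_truth()].
#' @param rt_mean mean reaction time in seconds (>= 0).
#' @param rt_jitter reaction-time SD in seconds (>= 0).
#' @param spurious_rate accidental presses per second.
#' @param seed optional integer seed.
#' @return an `observer_annotations` table (not RT-corrected).
#' @export
simulate_observers <- function(gt, rt_mean = 0.9, rt_jitter = 0.2,
                               spurious_rate = 0, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  stopifnot_scalar(rt_mean, "rt_mean", nonneg = TRUE)
  stopifnot_scalar(rt_jitter, "rt_jitter", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (run in names(gt$boundary_times)) {
    b <- gt$boundary_times[[run]]
    p <- gt$salience_prob[[run]]
    dur <- gt$run_length[[run]]
    for (o in seq_len(gt$n_observers)) {
      hit <- stats::runif(length(b)) < p
      t <- b[hit] + rt_mean + stats::rnorm(sum(hit), 0, rt_jitter)
      if (spurious_rate > 0) {
        n_sp <- stats::rpois(1, spurious_rate * dur)
        t <- c(t, stats::runif(n_sp, 0, dur))
      }
      t <- sort(pmin(pmax(t, 0), dur - 1e-9))
      if (length(t))
        rows[[length(rows) + 1L]] <- data.frame(
          observer_id = sprintf("o%02d", o), run_id = run, press_time_s = t)
    }
  }
  if (!length(rows))
    return(observer_annotations(character(), character(), numeric()))
  df <- do.call(rbind, rows)
  observer_annotations(df$observer_id, df$run_id, df$press_time_s)
}

#' Simulate ROI BOLD time courses at true boundaries
#'
#' Each participant's signal is the sum of HRF-convolved sticks at the true
#' boundary times (weighted by the per-boundary amplitudes), a low-frequency
#' cosine drift whose periods all exceed the 256 s high-pass cutoff (so the
#' cosine confound set removes it by construction), and AR(1) Gaussian noise
#' with stationary SD `noise_sd`.
#'
#' @param gt a [ground_truth()].
#' @param noise_sd stationary noise SD.
#' @param ar1 lag-1 autocorrelation in [0, 1).
#' @param drift_amp drift coefficient SD (0 disables drift).
#' @param spec an [hrf_spec()].
#' @param seed optional integer seed.
#' @return list with `tcs` (participant -> run -> [roi_tc()]), `clean`
#'   (run -> noiseless signal), `design` (run -> per-boundary event design
#'   columns) and the `gt`.
#' @export
simulate_bold <- function(gt, noise_sd = 1, ar1 = 0.3, drift_amp = 1,
                          spec = hrf_spec(), seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (ar1 < 0 || ar1 >= 1) stop("'ar1' must be in [0, 1)")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  tr <- gt$tr
  clean <- list(); designs <- list()
  for (run in names(gt$boundary_times)) {
    n_tr <- floor(gt$run_length[[run]] / tr)
    b <- gt$boundary_times[[run]]
    if (length(b)) {
      X <- sapply(b, function(t0) convolve_sticks(t0, 1, n_tr, tr, spec))
      X <- matrix(X, nrow = n_tr)
      clean[[run]] <- as.vector(X %*% gt$amplitudes[[run]])
    } else {
      X <- matrix(numeric(0), nrow = n_tr, ncol = 0)
      clean[[run]] <- numeric(n_tr)
    }
    designs[[run]] <- X
  }
  tcs <- vector("list", gt$n_participants)
  names(tcs) <- sprintf("p%03d", seq_len(gt$n_participants))
  for (p in names(tcs)) {
    tcs[[p]] <- list()
    for (run in names(clean)) {
      n_tr <- length(clean[[run]])
      drift <- numeric(n_tr)
      if (drift_amp > 0) {
        C <- cosine_basis(n_tr, tr, cutoff = 256)
        if (ncol(C))
          drift <- as.vector(C %*% stats::rnorm(ncol(C), 0, drift_amp))
      }
      noise <- numeric(n_tr)
      if (noise_sd > 0) {
        w <- stats::rnorm(n_tr, 0, noise_sd * sqrt(1 - ar1^2))
        noise[1] <- stats::rnorm(1, 0, noise_sd)
        for (t in seq_len(n_tr)[-1]) noise[t] <- ar1 * noise[t - 1] + w[t]
      }
      tcs[[p]][[run]] <- roi_tc(clean[[run]] + drift + noise, tr = tr,
                                run_id = run, participant_id = p)
    }
  }
  list(tcs = tcs, clean = clean, design = designs, gt = gt)
}

#' Simulate multi-voxel patterns with piecewise-constant event structure
#'
#' Each event has a random mean pattern; within an event all time points
#' share that mean, plus iid Gaussian noise.
#'
#' @param n_voxels number of voxels.
#' @param event_starts TR indices (>= 2) at which a new event begins; the
#'   first event starts at TR 1 implicitly.
#' @param n_tr total number of TRs.
#' @param noise_sd iid noise SD.
#' @param seed optional integer seed.
#' @return voxel x TR matrix with attribute `event_starts`.
#' @export
simulate_patterns <- function(n_voxels, event_starts, n_tr, noise_sd = 0.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  event_starts <- sort(unique(as.integer(event_starts)))
  if (length(event_starts) && (min(event_starts) < 2L || max(event_starts) > n_tr))
    stop("event_starts must lie in 2..n_tr")
  starts <- c(1L, event_starts)
  ends <- c(event_starts - 1L, n_tr)
  M <- matrix(0, n_voxels, n_tr)
  for (e in seq_along(starts)) {
    mu <- stats::rnorm(n_voxels)
    M[, starts[e]:ends[e]] <- mu
  }
  M <- M + matrix(stats::rnorm(n_voxels * n_tr, 0, noise_sd), n_voxels, n_tr)
  attr(M, "event_starts") <- event_starts
  M
}

#' Simulate toy film media: frames with scene cuts and per-scene audio
#'
#' Frames are small random textures, constant within a scene and redrawn at
#' each cut; audio is a per-scene mixture of pure tones, switching at each
#' cut. Scene luminance and tone frequencies can be pinned for constructing
#' exact-valued fixtures.
#'
#' @param run_length seconds.
#' @param cut_times scene-cut times in seconds (strictly increasing, within
#'   the run).
#' @param frame_rate frames per second.
#' @param audio_rate audio samples per second.
#' @param width,height frame size in pixels (kept small so brute-force
#'   similarity oracles run in seconds).
#' @param scene_luminance optional vector (one per scene) of mean frame
#'   intensities in (0, 1).
#' @param scene_freqs optional list (one per scene) of tone frequencies (Hz).
#' @param out_dir optional directory: frames written as PNG, audio as 16-bit
#'   PCM WAV, ground truth as a JSON sidecar.
#' @param seed optional integer seed.
#' @return list with `frames` (list of height x width matrices in [0,1]),
#'   `frame_times`, `audio`, `audio_rate`, `cut_times`, `scene_luminance`,
#'   `scene_freqs`.
#' @export
simulate_media <- function(run_length, cut_times, frame_rate = 5,
                           audio_rate = 8000, width = 32, height = 24,
                           scene_luminance = NULL, scene_freqs = NULL,
                           out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cut_times <- sort(cut_times)
  if (length(cut_times) && (min(cut_times) <= 0 || max(cut_times) >= run_length))
    stop("cut_times must lie strictly inside (0, run_length)")
  n_scenes <- length(cut_times) + 1L
  if (is.null(scene_luminance))
    scene_luminance <- stats::runif(n_scenes, 0.3, 0.7)
  if (is.null(scene_freqs))
    scene_freqs <- lapply(seq_len(n_scenes), function(i)
      sample(c(220, 330, 440, 660, 880, 1320, 1760, 2640), 2))
  scene_of <- function(t) findInterval(t, cut_times) + 1L

  frame_times <- seq(0, run_length - 1 / frame_rate, by = 1 / frame_rate)
  # texture amplitude kept narrow so re-centring to the scene luminance never
  # clips: frame means then equal scene_luminance exactly
  textures <- lapply(seq_len(n_scenes), function(s) {
    tx <- matrix(stats::runif(height * width, 0, 0.4), height, width)
    tx <- tx - mean(tx) + scene_luminance[s]
    pmin(pmax(tx, 0), 1)
  })
  frames <- lapply(frame_times, function(t) textures[[scene_of(t)]])

  t_audio <- seq(0, run_length - 1 / audio_rate, by = 1 / audio_rate)
  scene_idx <- scene_of(t_audio)
  audio <- numeric(length(t_audio))
  for (s in seq_len(n_scenes)) {
    sel <- scene_idx == s
    for (f in scene_freqs[[s]])
      audio[sel] <- audio[sel] + sin(2 * pi * f * t_audio[sel])
    audio[sel] <- audio[sel] / (length(scene_freqs[[s]]) * 1.5)
  }

  out <- list(frames = frames, frame_times = frame_times,
              frame_rate = frame_rate, audio = audio,
              audio_rate = audio_rate, cut_times = cut_times,
              scene_luminance = scene_luminance, scene_freqs = scene_freqs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(frames))
      png::writePNG(frames[[i]],
                    file.path(out_dir, sprintf("frame%05d.png", i)))
    write_wav(audio, file.path(out_dir, "audio.wav"), rate = audio_rate)
    jsonlite::write_json(
      list(run_length = run_length, cut_times = cut_times,
           frame_rate = frame_rate, audio_rate = audio_rate,
           scene_luminance = scene_luminance),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
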