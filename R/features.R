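# Frame-similarity measures weighting pixel comparisons by spatial proximity
# (a Gaussian kernel matrix G over pixel positions), plus histogram,
# luminance, audio-spectral and volume change measures, boundary-window
# maximization, SVD compaction and shot-annotation flags.

# Gaussian proximity kernel over pixel offsets, truncated to a square
# neighborhood of half-width `radius` (the default 9x9 window has radius 4);
# beyond that the weights are numerically negligible at sigma ~ 1.
gauss_kernel <- function(sigma = 1, radius = 4L) {
  d <- seq(-radius, radius)
  K <- outer(d, d, function(dy, dx)
    exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2))
  K
}

# 2D correlation of image with kernel (zero padding): out[i,j] =
# sum_k K[k] * img[i + dy_k, j + dx_k]
conv2_kernel <- function(img, K) {
  r <- (nrow(K) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (a in seq_len(nrow(K))) {
    dy <- a - r - 1L
    y_lo <- max(1L, 1L - dy); y_hi <- min(h, h - dy)
    if (y_lo > y_hi) next
    ys <- y_lo:y_hi
    for (b in seq_len(ncol(K))) {
      kv <- K[a, b]
      if (kv == 0) next
      dx <- b - r - 1L
      x_lo <- max(1L, 1L - dx); x_hi <- min(w, w - dx)
      if (x_lo > x_hi) next
      xs <- x_lo:x_hi
      out[ys, xs] <- out[ys, xs] + kv * img[ys + dy, xs + dx, drop = FALSE]
    }
  }
  out
}

# G-weighted inner product <x, G y> via kernel convolution; per-channel sum
g_inner <- function(x, y, K) {
  if (length(dim(x)) == 3L) {
    sum(vapply(seq_len(dim(x)[3]), function(c)
      sum(x[, , c] * conv2_kernel(y[, , c], K)), numeric(1)))
  } else {
    sum(x * conv2_kernel(y, K))
  }
}

check_frames <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("frames differ in shape")
  invisible(TRUE)
}

#' Spatially-weighted image Euclidean distance (IMED)
#'
#' `d^2 = sum_ij g_ij (x_i - y_i)(x_j - y_j)` with Gaussian proximity weights
#' `g_ij`, truncated to a square neighborhood around each pixel. Less
#' sensitive to small frame-to-frame movements than the plain pixelwise
#' distance. RGB frames: the quadratic form is computed per channel and
#' summed before the square root.
#'
#' @param frame_a,frame_b matrices (grayscale) or h x w x 3 arrays (RGB) of
#'   equal shape.
#' @param sigma Gaussian width in pixels.
#' @param radius neighborhood half-width in pixels (4 gives the 9 x 9
#'   window).
#' @return nonnegative distance.
#' @export
imed <- function(frame_a, frame_b, sigma = 1, radius = 4L) {
  check_frames(frame_a, frame_b)
  e <- frame_a - frame_b
  K <- gauss_kernel(sigma, radius)
  sqrt(max(0, g_inner(e, e, K)))
}

#' Spatially-weighted image normalized cross-correlation (IMNCC)
#'
#' `<x, G y> / sqrt(<x, G x> <y, G y>)` with the same Gaussian proximity
#' weighting as [imed()]; 1 for identical frames. RGB frames: numerator and
#' the two norms are summed over channels before normalization.
#'
#' @inheritParams imed
#' @return correlation in [-1, 1].
#' @export
imncc <- function(frame_a, frame_b, sigma = 1, radius = 4L) {
  check_frames(frame_a, frame_b)
  K <- gauss_kernel(sigma, radius)
  num <- g_inner(frame_a, frame_b, K)
  den <- sqrt(g_inner(frame_a, frame_a, K) * g_inner(frame_b, frame_b, K))
  if (den == 0) stop("IMNCC undefined for an all-zero frame")
  min(1, max(-1, num / den))
}

#' Euclidean distance between frame intensity histograms
#'
#' Histograms are computed on `n_bins` equal bins over [0, 1] per channel;
#' for RGB frames the per-channel histograms are concatenated before the
#' distance. Invariant to any spatial rearrangement of pixels.
#'
#' @inheritParams imed
#' @param n_bins histogram bins per channel.
#' @return nonnegative distance (in pixel counts).
#' @export
hist_distance <- function(frame_a, frame_b, n_bins = 256L) {
  check_frames(frame_a, frame_b)
  hist_of <- function(x) {
    if (length(dim(x)) == 3L) {
      unlist(lapply(seq_len(dim(x)[3]), function(c)
        tabulate(pmin(floor(x[, , c] * n_bins) + 1L, n_bins), n_bins)))
    } else {
      tabulate(pmin(floor(x * n_bins) + 1L, n_bins), n_bins)
    }
  }
  sqrt(sum((hist_of(frame_a) - hist_of(frame_b))^2))
}

#' Absolute difference in mean frame luminance
#'
#' Luminance is the unweighted mean intensity over all pixels (and channels).
#'
#' @inheritParams imed
#' @return nonnegative difference.
#' @export
luminance_diff <- function(frame_a, frame_b) {
  check_frames(frame_a, frame_b)
  abs(mean(frame_a) - mean(frame_b))
}

#' Most-changed frame pair across a boundary
#'
#' Evaluates `measure` on every cross pair of frames from the 1 s window
#' before the boundary (`[t - window, t)`) and the 1 s window after
#' (`[t, t + window)`). Distances are maximized (the largest change);
#' correlations are minimized (the most-changed pair). Windows are truncated
#' at the run edges.
#'
#' @param frames list of frames.
#' @param frame_times numeric frame timestamps in seconds.
#' @param boundary_time boundary time in seconds.
#' @param measure function of two frames.
#' @param window window length in seconds.
#' @param mode `"max-dist"` or `"min-corr"`.
#' @return scalar (NA when either window is empty).
#' @export
window_change <- function(frames, frame_times, boundary_time, measure,
                          window = 1, mode = c("max-dist", "min-corr")) {
  mode <- match.arg(mode)
  pre <- which(frame_times >= boundary_time - window & frame_times < boundary_time)
  post <- which(frame_times >= boundary_time & frame_times < boundary_time + window)
  if (!length(pre) || !length(post)) return(NA_real_)
  vals <- vapply(pre, function(i)
    vapply(post, function(j) measure(frames[[i]], frames[[j]]), numeric(1)),
    numeric(length(post)))
  if (mode == "max-dist") max(vals) else min(vals)
}

# Hann-windowed periodogram, one-sided, truncated at f_cutoff
periodogram_psd <- function(x, rate, f_cutoff = Inf) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- stats::fft(x * w)
  n_keep <- floor(n / 2) + 1L
  psd <- (Mod(X[seq_len(n_keep)])^2) / (rate * sum(w^2))
  freq <- (seq_len(n_keep) - 1L) * rate / n
  keep <- freq <= f_cutoff
  list(freq = freq[keep], psd = psd[keep])
}

#' Spectral similarity across a boundary
#'
#' Computes the power spectral density (Hann-windowed periodogram) of the
#' audio epochs immediately before and after the boundary, truncated at
#' `f_cutoff`, and returns the Pearson correlation and Euclidean distance
#' between the two PSD vectors.
#'
#' @param audio numeric waveform.
#' @param rate sample rate in Hz.
#' @param boundary_time boundary time in seconds.
#' @param epoch epoch length in seconds (default 0.5).
#' @param f_cutoff frequency cutoff in Hz (default 5000).
#' @return list with `psd_corr` and `psd_dist`.
#' @export
psd_measures <- function(audio, rate, boundary_time, epoch = 0.5,
                         f_cutoff = 5000) {
  i0 <- round(boundary_time * rate)
  n <- round(epoch * rate)
  pre_idx <- max(1L, i0 - n + 1L):i0
  post_idx <- (i0 + 1L):min(length(audio), i0 + n)
  if (length(pre_idx) < 8L || length(post_idx) < 8L)
    return(list(psd_corr = NA_real_, psd_dist = NA_real_))
  p1 <- periodogram_psd(audio[pre_idx], rate, f_cutoff)$psd
  p2 <- periodogram_psd(audio[post_idx], rate, f_cutoff)$psd
  m <- min(length(p1), length(p2))
  list(psd_corr = stats::cor(p1[seq_len(m)], p2[seq_len(m)]),
       psd_dist = sqrt(sum((p1[seq_len(m)] - p2[seq_len(m)])^2)))
}

#' Absolute volume change across a boundary
#'
#' Volume is the RMS amplitude (optionally mean-absolute) over the `window`
#' seconds before and after the boundary; the measure is the absolute
#' difference of the two.
#'
#' @inheritParams psd_measures
#' @param window window length in seconds (default 0.1).
#' @param type `"rms"` or `"mean-abs"`.
#' @return nonnegative volume difference.
#' @export
volume_diff <- function(audio, rate, boundary_time, window = 0.1,
                        type = c("rms", "mean-abs")) {
  type <- match.arg(type)
  vol <- function(x) if (type == "rms") sqrt(mean(x^2)) else mean(abs(x))
  i0 <- round(boundary_time * rate)
  n <- round(window * rate)
  pre <- audio[max(1L, i0 - n + 1L):i0]
  post <- audio[(i0 + 1L):min(length(audio), i0 + n)]
  abs(vol(pre) - vol(post))
}

#' Deterministic mean-pooling pyramid feature extractor
#'
#' A stand-in, multi-layer feature extractor for tests and demos: layer l is
#' the frame mean-pooled by a factor `2^(l-1)`. Any object with fields
#' `n_layers` and `features(frame) -> list of numeric arrays` can be used in
#' its place (e.g. an adapter around a pretrained network).
#'
#' @param n_layers number of pyramid levels.
#' @return a feature-extractor object.
#' @export
pyramid_extractor <- function(n_layers = 3L) {
  pool <- function(m, f) {
    h <- (nrow(m) %/% f) * f; w <- (ncol(m) %/% f) * f
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    nr <- h %/% f; nc <- w %/% f
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      out[i, j] <- mean(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    out
  }
  list(n_layers = as.integer(n_layers),
       features = function(frame) {
         if (length(dim(frame)) == 3L) frame <- apply(frame, c(1, 2), mean)
         lapply(seq_len(n_layers), function(l)
           if (l == 1L) frame else pool(frame, 2L^(l - 1L)))
       })
}

#' Per-layer feature correlations across a boundary
#'
#' For each layer of the extractor, computes the Pearson correlation between
#' the flattened representations of pre- and post-boundary frames, taking
#' the minimum over all cross pairs of the 1 s windows (the most-changed
#' pair), as for the other visual measures.
#'
#' @inheritParams window_change
#' @param extractor a feature extractor (see [pyramid_extractor()]).
#' @return numeric vector of length `extractor$n_layers`.
#' @export
layered_feature_corr <- function(frames, frame_times, boundary_time,
                                 extractor = pyramid_extractor(),
                                 window = 1) {
  layer_corr <- function(fa, fb) {
    la <- extractor$features(fa); lb <- extractor$features(fb)
    vapply(seq_len(extractor$n_layers), function(l) {
      a <- as.vector(la[[l]]); b <- as.vector(lb[[l]])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
  }
  pre <- which(frame_times >= boundary_time - window & frame_times < boundary_time)
  post <- which(frame_times >= boundary_time & frame_times < boundary_time + window)
  if (!length(pre) || !length(post))
    return(rep(NA_real_, extractor$n_layers))
  res <- matrix(NA_real_, extractor$n_layers, length(pre) * length(post))
  k <- 0L
  for (i in pre) for (j in post) {
    k <- k + 1L
    res[, k] <- layer_corr(frames[[i]], frames[[j]])
  }
  apply(res, 1, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
}

#' Compact correlated measures by singular value decomposition
#'
#' Standardizes the columns (optional), runs an SVD, and returns the scores
#' of the leading components that reach `variance_target` of the total
#' variance (or exactly `k` components).
#'
#' @param feature_matrix boundaries x measures numeric matrix.
#' @param variance_target fraction of variance to retain (ignored when `k`
#'   given).
#' @param k exact number of components, or `NULL`.
#' @param center,scale. standardize columns before the SVD.
#' @return matrix of component scores (columns `comp1`, ...), with
#'   attributes `variance_explained` and `n_components`.
#' @export
svd_compact <- function(feature_matrix, variance_target = 0.90, k = NULL,
                        center = TRUE, scale. = TRUE) {
  X <- as.matrix(feature_matrix)
  if (scale. && any(apply(X, 2, stats::sd) == 0))
    stop("cannot standardize a zero-variance column")
  X <- scale(X, center = center, scale = scale.)
  sv <- svd(X)
  var_expl <- sv$d^2 / sum(sv$d^2)
  m <- if (!is.null(k)) as.integer(k)
       else which(cumsum(var_expl) >= variance_target - 1e-12)[1]
  m <- min(m, length(sv$d))
  scores <- sv$u[, seq_len(m), drop = FALSE] %*%
    diag(sv$d[seq_len(m)], nrow = m)
  colnames(scores) <- paste0("comp", seq_len(m))
  attr(scores, "variance_explained") <- var_expl
  attr(scores, "n_components") <- m
  scores
}

#' Location / temporal-progression flags from shot annotations
#'
#' Each boundary inherits the flags of the shot transition it falls on: the
#' nearest shot onset within 1 TR. `isLoc` marks a change of location
#' relative to the preceding shot, `isTemp` the shot's temporal-progression
#' flag. When the two coincide for every boundary they are collapsed into a
#' single `isLocTemp` predictor (flagged via the `combined` attribute).
#'
#' @param boundaries consensus-boundary data frame (single run).
#' @param shot_table data frame with `onset_s`, `location_id`,
#'   `temporal_progression` (0/1).
#' @param tr repetition time in seconds (the matching window).
#' @return data frame with columns `isLoc`, `isTemp`, `isLocTemp`; attribute
#'   `combined` is TRUE when isLoc == isTemp throughout.
#' @export
shot_flags <- function(boundaries, shot_table, tr) {
  st <- shot_table[order(shot_table$onset_s), , drop = FALSE]
  loc_change <- c(0L, as.integer(st$location_id[-1] != st$location_id[-nrow(st)]))
  temp_flag <- as.integer(st$temporal_progression)
  n <- nrow(boundaries)
  isLoc <- integer(n); isTemp <- integer(n)
  for (i in seq_len(n)) {
    d <- abs(st$onset_s - boundaries$time[i])
    j <- which.min(d)
    if (d[j] <= tr) {
      isLoc[i] <- loc_change[j]
      isTemp[i] <- temp_flag[j]
    }
  }
  out <- data.frame(isLoc = isLoc, isTemp = isTemp,
                    isLocTemp = as.integer(isLoc | isTemp))
  attr(out, "combined") <- all(isLoc == isTemp)
  out
}

#' All perceptual covariates for a set of boundaries
#'
#' Convenience wrapper computing the visual (IMED, IMNCC, histogram,
#' luminance, layered features), auditory (PSD correlation/distance, volume)
#' and shot-annotation measures for every boundary of one run.
#'
#' @param boundaries consensus-boundary data frame (single run).
#' @param media a [simulate_media()]-style list (`frames`, `frame_times`,
#'   `audio`, `audio_rate`), or `NULL` to skip media measures.
#' @param shot_table optional shot-annotation table for [shot_flags()].
#' @param tr repetition time in seconds.
#' @param extractor feature extractor for [layered_feature_corr()].
#' @param sigma,radius IMED/IMNCC parameters.
#' @return data frame keyed by `boundary_id` with one column per covariate
#'   (`visDist`, `visCorr`, `visHistDist`, `lumDist`, `dcnn1..L`, `psdCorr`,
#'   `psdDist`, `absVolDiff`, and shot flags when available).
#' @export
boundary_covariates <- function(boundaries, media = NULL, shot_table = NULL,
                                tr = 2, extractor = pyramid_extractor(),
                                sigma = 1, radius = 4L) {
  n <- nrow(boundaries)
  run <- boundaries$run_id %||% rep("run1", n)
  out <- data.frame(boundary_id = sprintf("%s@%.3f", run, boundaries$time))
  if (!is.null(media)) {
    fr <- media$frames; ft <- media$frame_times
    out$visDist <- vapply(boundaries$time, function(t)
      window_change(fr, ft, t, function(a, b) imed(a, b, sigma, radius),
                    mode = "max-dist"), numeric(1))
    out$visCorr <- vapply(boundaries$time, function(t)
      window_change(fr, ft, t, function(a, b) imncc(a, b, sigma, radius),
                    mode = "min-corr"), numeric(1))
    out$visHistDist <- vapply(boundaries$time, function(t)
      window_change(fr, ft, t, hist_distance, mode = "max-dist"), numeric(1))
    out$lumDist <- vapply(boundaries$time, function(t)
      window_change(fr, ft, t, luminance_diff, mode = "max-dist"), numeric(1))
    dc <- t(vapply(boundaries$time, function(t)
      layered_feature_corr(fr, ft, t, extractor), numeric(extractor$n_layers)))
    colnames(dc) <- paste0("dcnn", seq_len(ncol(dc)))
    out <- cbind(out, dc)
    au <- media$audio; rate <- media$audio_rate
    pm <- lapply(boundaries$time, function(t) psd_measures(au, rate, t))
    out$psdCorr <- vapply(pm, `[[`, numeric(1), "psd_corr")
    out$psdDist <- vapply(pm, `[[`, numeric(1), "psd_dist")
    out$absVolDiff <- vapply(boundaries$time, function(t)
      volume_diff(au, rate, t), numeric(1))
  }
  if (!is.null(shot_table)) {
    out <- cbind(out, shot_flags(boundaries, shot_table, tr))
  }
  out
}
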