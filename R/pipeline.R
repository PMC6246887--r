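#' Analysis configuration
#'
#' Collects the constants of the analysis. Defaults are the standard
#' operating values: 0.9 s reaction-time correction, 10 s run-end margin,
#' 6 s minimum boundary gap for single-trial GLMs, 1000 permutations,
#' 1 TR / 2 TR match windows for the boundary / pattern-shift analyses,
#' a [-2, 12] s FIR window and a 256 s high-pass cutoff.
#'
#' @param tr repetition time in seconds.
#' @param rt reaction time subtracted from keypresses (seconds).
#' @param run_end_margin seconds trimmed from the run end.
#' @param min_boundary_gap minimum boundary separation for single-trial
#'   estimation (seconds).
#' @param n_perm permutations for all permutation nulls.
#' @param match_window_tr boundary-match window (TRs).
#' @param ag_match_window_tr pattern-shift match window (TRs).
#' @param fir_range FIR window in seconds.
#' @param highpass_cutoff cosine-set cutoff (seconds).
#' @param seed integer seed governing all randomness.
#' @param n_participants,n_observers synthetic cohort sizes for the demo.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(tr = 2.47, rt = 0.9, run_end_margin = 10,
                            min_boundary_gap = 6, n_perm = 1000,
                            match_window_tr = 1, ag_match_window_tr = 2,
                            fir_range = c(-2, 12), highpass_cutoff = 256,
                            seed = 1L, n_participants = 30L,
                            n_observers = 16L) {
  cfg <- list(tr = tr, rt = rt, run_end_margin = run_end_margin,
              min_boundary_gap = min_boundary_gap, n_perm = n_perm,
              match_window_tr = match_window_tr,
              ag_match_window_tr = ag_match_window_tr,
              fir_range = fir_range, highpass_cutoff = highpass_cutoff,
              seed = as.integer(seed),
              n_participants = as.integer(n_participants),
              n_observers = as.integer(n_observers))
  for (nm in c("tr", "rt", "run_end_margin", "min_boundary_gap", "n_perm",
               "match_window_tr", "ag_match_window_tr", "highpass_cutoff"))
    stopifnot_scalar(cfg[[nm]], nm, nonneg = TRUE)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  raw <- serialize(unclass(config)[order(names(unclass(config)))], NULL,
                   version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}

#' Ground truth used by the demo pipeline
#'
#' An 8-minute single-run film analogue: 15 boundaries at irregular
#' intervals, detection probabilities spanning low to high salience, and
#' BOLD amplitudes increasing with salience (so the salience modulation is
#' recoverable downstream).
#'
#' @param tr repetition time in seconds.
#' @param n_participants,n_observers cohort sizes.
#' @return a [ground_truth()].
#' @export
demo_ground_truth <- function(tr = 2.47, n_participants = 30L,
                              n_observers = 16L) {
  times <- c(22, 51, 74, 103, 128, 160, 185, 211, 240, 272, 301, 330,
             361, 395, 428)
  sal <- rep(c(0.35, 0.65, 0.95), 5)
  ground_truth(boundary_times = times, run_length = 480, tr = tr,
               salience_prob = sal, amplitudes = 0.5 + sal,
               n_participants = n_participants, n_observers = n_observers)
}

#' Run the full analysis end-to-end
#'
#' Orchestrates the pipeline: observer simulation (or supplied annotations)
#' -> consensus boundaries -> BOLD simulation (or supplied time courses) ->
#' boundary-amplitude permutation test -> FIR time courses -> single-trial
#' betas -> mixed models -> multi-voxel pattern HMM, shift classification
#' and peri-shift responses -> greedy data-driven events and specificity
#' test. When `inputs` is `NULL` every input is synthesized from
#' [demo_ground_truth()] under the config seed. Optionally computes media
#' covariates and covariate-adjusted models (`with_media = TRUE`).
#'
#' @param config a [pipeline_config()].
#' @param inputs optional list with `annotations` (an
#'   `observer_annotations`), `tcs` (participant -> run -> [roi_tc()]),
#'   `patterns` (voxel x TR matrix), `run_length` (seconds); missing pieces
#'   are simulated.
#' @param with_media also simulate media and fit single-covariate models.
#' @param out_dir optional output directory: boundary/beta TSVs, a JSON
#'   report carrying the config hash, and figure PNGs are written there.
#' @return list of class `filmseg_pipeline` with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         with_media = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  gt <- inputs$gt %||% demo_ground_truth(tr = config$tr,
                                         n_participants = config$n_participants,
                                         n_observers = config$n_observers)
  run_length <- inputs$run_length %||% unname(gt$run_length[1])

  # --- consensus boundaries -------------------------------------------------
  ann <- inputs$annotations %||%
    simulate_observers(gt, rt_mean = config$rt, rt_jitter = 0.2)
  boundaries <- consensus_boundaries(ann, tr = config$tr, rt = config$rt,
                                     run_duration = run_length,
                                     margin = config$run_end_margin)
  if (nrow(boundaries) < 2L) stop("pipeline aborted at stage 'annotations': ",
                                  "fewer than 2 consensus boundaries")

  # --- BOLD -----------------------------------------------------------------
  sim <- NULL
  if (is.null(inputs$tcs)) {
    sim <- simulate_bold(gt, noise_sd = 1, ar1 = 0.3, drift_amp = 0.5)
    tcs <- sim$tcs
  } else tcs <- inputs$tcs
  run <- boundaries$run_id[1]
  tcs_run <- lapply(tcs, `[[`, run)
  group_tc <- zscore_and_average(tcs_run)

  # --- sensitivity: amplitude permutation test ------------------------------
  amp_test <- amplitude_null(group_tc, boundaries, tr = config$tr,
                             n_perm = config$n_perm,
                             highpass_cutoff = config$highpass_cutoff)

  # --- FIR ------------------------------------------------------------------
  fir <- fir_timecourse(tcs_run, boundaries, tr = config$tr,
                        fir_range = config$fir_range)

  # --- single-trial betas + mixed models ------------------------------------
  betas <- single_trial_betas(tcs, boundaries, tr = config$tr,
                              min_gap = config$min_boundary_gap,
                              highpass_cutoff = config$highpass_cutoff)
  lmm_salience <- fit_lmm(betas, "salience")
  lmm_nobs <- fit_lmm(betas, "nObservers")

  # --- pattern HMM ----------------------------------------------------------
  n_tr <- length(group_tc$values)
  boundary_trs <- pmin(pmax(round(boundaries$time / config$tr) + 1L, 2L), n_tr)
  patterns <- inputs$patterns %||%
    simulate_patterns(40, boundary_trs, n_tr, noise_sd = 0.5)
  hmm <- fit_event_hmm(patterns, k_events = nrow(boundaries) + 1L)
  shifts <- classify_shifts(hmm$shift_times, boundaries, tr = config$tr,
                            window_tr = config$ag_match_window_tr)
  peri <- peri_shift_response(group_tc, shifts, n_perm = config$n_perm)

  # --- data-driven events ---------------------------------------------------
  filt_tc <- roi_tc(
    zscore_vec(qr.resid(qr(cbind(1, cosine_basis(n_tr, config$tr,
                                                 config$highpass_cutoff))),
                        group_tc$values)),
    tr = config$tr, run_id = run, participant_id = "group", zscored = TRUE)
  events <- greedy_event_search(filt_tc, k = nrow(boundaries))
  spec_test <- specificity_test(events, boundaries, run_duration = run_length,
                                window_tr = config$match_window_tr,
                                n_perm = config$n_perm)

  # --- media covariates (optional) ------------------------------------------
  covars <- NULL; cov_models <- NULL
  if (with_media) {
    media <- inputs$media %||%
      simulate_media(run_length, cut_times = gt$boundary_times[[1]],
                     frame_rate = 4, audio_rate = 4000,
                     width = 24, height = 18)
    covars <- boundary_covariates(boundaries, media, tr = config$tr)
    tab <- merge(betas, covars, by = "boundary_id")
    cov_models <- covariate_models(tab, covariates = c("visDist", "lumDist",
                                                       "psdCorr", "absVolDiff"),
                                   effect = "salience")
  }

  result <- structure(list(
    config = config, config_hash = config_hash(config),
    ground_truth = gt, annotations = ann, boundaries = boundaries,
    group_tc = group_tc, amplitude_test = amp_test, fir = fir,
    betas = betas, lmm_salience = lmm_salience, lmm_nobservers = lmm_nobs,
    hmm = hmm, shifts = shifts, peri_shift = peri,
    events = events, specificity = spec_test,
    covariates = covars, covariate_models = cov_models),
    class = "filmseg_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
#' @method print filmseg_pipeline
print.filmseg_pipeline <- function(x, ...) {
  cat("<filmseg_pipeline>\n")
  cat(sprintf("  consensus boundaries: %d (threshold %d)\n",
              nrow(x$boundaries), attr(x$boundaries, "threshold")))
  cat(sprintf("  boundary amplitude: %.3f (permutation p = %.4g)\n",
              x$amplitude_test$observed, x$amplitude_test$p))
  cat(sprintf("  salience model: F(%g, %.1f) = %.2f, p = %.3g\n",
              x$lmm_salience$df_num, x$lmm_salience$df_den,
              x$lmm_salience$F, x$lmm_salience$p))
  cat(sprintf("  data-driven match: %d/%d (%.0f%%), p = %.4g\n",
              x$specificity$matches, length(x$events$event_trs),
              100 * x$specificity$fraction, x$specificity$perm$p))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_boundaries(result$boundaries, file.path(out_dir, "boundaries.tsv"))
  utils::write.table(result$betas, file.path(out_dir, "betas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(run_id = result$boundaries$run_id[1],
                   event_tr = result$events$event_trs,
                   event_time_s = result$events$event_times,
                   beta = result$events$betas,
                   matched = result$specificity$matched)
  utils::write.table(ev, file.path(out_dir, "datadriven_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    config = unclass(result$config),
    config_hash = result$config_hash,
    n_boundaries = nrow(result$boundaries),
    threshold = attr(result$boundaries, "threshold"),
    amplitude = result$amplitude_test$observed,
    amplitude_p = result$amplitude_test$p,
    salience_F = result$lmm_salience$F,
    salience_p = result$lmm_salience$p,
    nobservers_F = result$lmm_nobservers$F,
    nobservers_p = result$lmm_nobservers$p,
    datadriven_matches = result$specificity$matches,
    datadriven_fraction = result$specificity$fraction,
    datadriven_p = result$specificity$perm$p)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  grDevices::png(file.path(out_dir, "fir_curves.png"), 720, 480)
  plot_fir(result$fir)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "peri_shift.png"), 720, 480)
  plot_peri_shift(result$peri_shift, result$config$tr)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "datadriven_fit.png"), 960, 480)
  plot_datadriven(result$group_tc, result$events, result$specificity)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Plot FIR peri-boundary curves per salience bin
#'
#' @param fir result of [fir_timecourse()].
#' @export
plot_fir <- function(fir) {
  cols <- c(low = "#4477aa", med = "#ccbb44", high = "#aa3377",
            all = "#333333")
  graphics::matplot(fir$lags, t(fir$mean), type = "l", lty = 1, lwd = 2,
                    col = cols[fir$conditions],
                    xlab = "time from boundary (s)", ylab = "FIR estimate")
  graphics::abline(v = 0, col = "grey40")
  graphics::legend("topright", legend = fir$conditions, lwd = 2,
                   col = cols[fir$conditions], bty = "n")
  invisible(NULL)
}

#' Plot peri-shift averaged responses for match / non-match shifts
#'
#' @param peri result of [peri_shift_response()].
#' @param tr repetition time in seconds.
#' @export
plot_peri_shift <- function(peri, tr) {
  m <- rbind(peri$curves$match, peri$curves$nonmatch)
  graphics::matplot(peri$lags * tr, t(m), type = "l", lty = 1, lwd = 2,
                    col = c("#aa3377", "grey50"),
                    xlab = "time from pattern shift (s)",
                    ylab = "z-scored response")
  graphics::abline(v = 0, col = "grey40")
  graphics::legend("topright", legend = c("match", "non-match"), lwd = 2,
                   col = c("#aa3377", "grey50"), bty = "n")
  invisible(NULL)
}

#' Plot the group time course with data-driven events
#'
#' @param tc the group [roi_tc()].
#' @param events an `roi_event_set`.
#' @param spec_test result of [specificity_test()].
#' @export
plot_datadriven <- function(tc, events, spec_test) {
  t <- (seq_along(tc$values) - 1) * tc$tr
  graphics::plot(t, tc$values, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "signal")
  graphics::abline(v = events$event_times,
                   col = ifelse(spec_test$matched, "#ee7733", "grey70"))
  invisible(NULL)
}
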