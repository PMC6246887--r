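# filmseg

Event-boundary sensitivity and specificity analysis for naturalistic
(film-viewing) fMRI.

## The problem

When people watch a film, they segment the continuous stream into discrete
events, and independent observers largely agree on where the boundaries
fall. `filmseg` is for researchers asking whether a region of interest —
canonically the hippocampus — responds to those subjective boundaries
during continuous viewing, whether that response scales with *boundary
salience* (the number of observers endorsing a boundary), whether it
survives adjustment for audiovisual change, and whether the region's
strongest spontaneous responses are *specific* to boundaries.

## The methods at its core

* **Consensus boundaries.** Keypress logs from independent observers are
  RT-corrected (default 0.9 s), merged in two passes (presses within 1 TR
  become one boundary at the mean time; adjacent multi-observer boundaries
  under 2 TRs are merged once more, exactly one pass so chains cannot
  collapse), trimmed at the run end, thresholded so the boundary count
  matches the per-observer mean press count, and split into low/med/high
  salience bins of approximately equal size.
* **Boundary-evoked amplitudes.** A GLM with HRF-convolved stick
  regressors, `y = Xβ + ε`, where X holds either one column for all
  boundaries, one per boundary (single-trial betas; pairs closer than 6 s
  excluded), or a condition-by-lag FIR basis on a 1 s grid; a 256 s cosine
  set absorbs drift. Significance comes from permuting the event durations
  (the inter-boundary intervals) and recomputing, p = (1 + #{|null| ≥
  |obs|}) / (n + 1).
* **Mixed models.** `beta ~ salience + (1|participant) + (1|boundary)`
  (or nObservers in place of the 1/2/3 salience score), REML via lme4,
  type-III F with Satterthwaite df via lmerTest, marginal R², single- and
  full-covariate adjustment, and a Holm–Bonferroni ROI sweep.
* **Pattern shifts.** A left-to-right Gaussian HMM with K events segments
  multi-voxel patterns; shifts matched to boundaries (≤ 2 TRs, boundary
  first) separate boundary-driven from spontaneous pattern change.
* **Data-driven events.** A greedy search adds the stick regressor (one
  candidate per TR) that most reduces the RSS, under positivity and
  no-sign-flip constraints, and the detected events are tested for overlap
  with consensus boundaries against a duration-shuffled null.

A synthetic-data module generates observer logs, BOLD series, voxel
patterns and toy media (PNG frames + WAV audio) with known ground truth, so
the full chain is testable without any data download.

## Worked example

```r
library(filmseg)

cfg <- pipeline_config(tr = 2.47, n_perm = 999, seed = 11,
                       n_participants = 20)
res <- run_pipeline(cfg)   # fully synthetic demo, ~3 s
print(res)
#> <filmseg_pipeline>
#>   consensus boundaries: 10 (threshold 8)
#>   boundary amplitude: 1.172 (permutation p = 0.001)
#>   salience model: F(1, 179.0) = 5.68, p = 0.0182
#>   data-driven match: 8/10 (80%), p = 0.001
```

Reading the output: 16 simulated observers yielded 10 consensus boundaries
(those endorsed by ≥ 8 observers). The group hippocampal-style signal shows
a boundary-locked amplitude of 1.17 that no duration-shuffled layout
matched (p = 0.001 at 999 permutations); single-trial amplitudes increase
with salience (F test of the linear trend); and 8 of the 10 data-driven
events — chosen only to explain the signal — fall within 1 TR of a
consensus boundary, far above chance.

Individual stages are plain functions: `consensus_boundaries()`,
`build_design()` / `estimate_amplitude()` / `single_trial_betas()` /
`fir_timecourse()`, `amplitude_null()`, `boundary_covariates()`,
`fit_lmm()` / `covariate_models()` / `roi_sweep()`, `fit_event_hmm()` /
`classify_shifts()` / `peri_shift_response()`, `greedy_event_search()` /
`specificity_test()`, with TSV/NIfTI/PNG/WAV readers and writers alongside.

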