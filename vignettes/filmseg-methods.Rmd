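---
title: "Event-boundary analysis of naturalistic fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-boundary analysis of naturalistic fMRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmseg)
```

## The scientific question

When people watch a film, they spontaneously segment the continuous stream
into discrete events, and independent observers agree remarkably well about
where one event ends and the next begins. `filmseg` implements a complete
analysis chain for asking whether the BOLD signal of a region of interest
(canonically the hippocampus) is *sensitive* to these subjective event
boundaries — responding more strongly the more observers endorse a boundary —
and *specific* to them — such that the region's strongest spontaneous
responses coincide with boundaries rather than with other moments.

The chain has five stages, each usable on its own:

1. **Consensus boundaries** from observer keypress logs (`annotations` layer).
2. **Boundary-evoked amplitudes** via HRF stick-function GLMs, FIR
   deconvolution, and duration-shuffling permutation nulls.
3. **Perceptual covariates** quantifying audiovisual change at each boundary.
4. **Crossed random-effects models** of single-trial amplitudes against
   boundary salience, with covariate adjustment and an ROI sweep.
5. **Pattern segmentation and data-driven event detection**: an
   ordered-event HMM on multi-voxel patterns, and a greedy residual-
   minimisation search for the time points that best explain the ROI signal.

## Consensus boundary construction

Raw keypresses are first shifted earlier by a fixed reaction time
(default 0.9 s, clamped at zero). Merging then proceeds in two passes:

* **Pass 1** clusters presses within 1 TR of one another. We use
  single-linkage chaining in time order: a press joins the current cluster
  while it is within 1 TR of the previous member. An observer contributing
  several presses to one cluster is counted once, with their times averaged
  first (the observer count means "number of observers"). A fixed-anchor
  window would be a defensible alternative; chaining is the simpler reading
  and is the default.
* **Pass 2** merges *adjacent pairs* of pass-1 boundaries that are each
  endorsed by at least two observers and lie less than 2 TRs apart. It runs
  exactly once, left to right, each boundary participating in at most one
  merge. Running it to convergence would let chains of pairwise-close
  boundaries collapse into a single boundary averaged over a span several
  times the merge radius, which is precisely the artifact the two-pass
  design avoids.

Boundaries within 10 s of the run end are removed (their responses cannot be
estimated). The observer-count threshold is chosen so that the number of
retained boundaries is closest to the mean number of presses per observer —
the data's own estimate of the true boundary count; ties go to the lower,
more inclusive threshold.

Salience bins partition the sorted distinct observer counts into three
contiguous ranges minimising the squared deviation of the bin counts from
N/3. Ties are broken by minimising the difference between the low- and
high-bin counts; on the short-film tallies this uniquely selects the 7/5/7
split over the equally-balanced 7/7/5 alternative. With fewer than three
distinct counts the binning is flagged degenerate rather than forced.

```{r salience}
tally <- c(`5` = 3, `6` = 4, `8` = 1, `10` = 2, `12` = 2, `13` = 2,
           `14` = 2, `15` = 2, `16` = 1)
b <- data.frame(run_id = "run1", time = seq_len(19) * 25,
                n_observers = rep(as.integer(names(tally)), tally),
                salience_bin = NA)
table(bin_salience(b)$salience_bin)
```

## Hemodynamic modelling

The canonical HRF is a double gamma with unit peak: response gamma with
shape 6 and dispersion 1 s (mode at 5 s), undershoot gamma with shape 16,
relative undershoot amplitude 1/6, 32 s support. These are the de facto
canonical parameters; all are configurable through `hrf_spec()`. Sticks are
placed at real-valued boundary times on a microtime grid of 16 bins per TR
and the convolved regressor is sampled at the middle bin of each TR,
matching slice-time correction to the middle slice. Low-frequency drift is
handled inside the GLM by a discrete cosine set with a 256 s cutoff.

Three design schemes share this code path: one column for all boundaries
(the sensitivity test), one column per boundary (single-trial estimation;
`least-squares-all`, the literal reading of "a separate predictor for each
boundary"), and a condition-by-lag FIR basis on a 1 s grid from −2 to 12 s
(after linear interpolation of the signal to 1 s resolution). For
single-trial estimation, *both* members of any boundary pair closer than
6 s are removed — responses that close cannot be dissociated, and symmetric
removal avoids an arbitrary choice of which to keep.

## Permutation nulls

Significance of the boundary-evoked amplitude is assessed against
reshuffles of the *event durations*: the intervals from run start to the
first boundary and between consecutive boundaries are permuted and
cumulatively summed, preserving the boundary count, the interval multiset
and the occupied span. The onset interval participates in the shuffle (the
tail after the last boundary is held fixed, preserving run length exactly);
`include_onset = FALSE` gives the variant with a fixed onset. p-values use
the add-one estimator (1 + #{|null| ≥ |observed|}) / (n_perm + 1), so a
result stronger than every permutation reports p = 1/(n+1), never 0. In
multi-run data the shuffle is within run and the statistic is a single
pooled GLM with run-wise confounds.

The same machinery drives the match-count test used for data-driven events:
the reference boundaries are duration-shuffled and the one-to-one match
count (greedy, by ascending temporal distance, each event matched at most
once) is recomputed. Because the match count is a small integer and the
shuffled references share both the interval multiset and the test events
with the observed statistic, this test is *conservative*: its empirical
false-positive rate at a nominal 0.05 sits below 0.05, most visibly when
events are sparse. The package's calibration suite therefore measures it
under a moderate density (20 events in a 600 s run, 2 s window) where the
discreteness is mild; the guaranteed property is validity (never
anti-conservative), not exactness.

## Mixed models

Single-trial amplitudes are modelled with crossed random intercepts for
participant and boundary (the stimulus-as-fixed-effect fallacy is the
motivation: boundaries are a sample of items). Salience enters as an
ordinal 1/2/3 score — the model tests a linear trend across bins — and the
raw observer count enters unbinned in a parallel model; the two are never
included together. Fits use REML via `lme4`, with type-III F tests and
Satterthwaite denominator degrees of freedom via `lmerTest`. Effect size is
the marginal R² (fixed-effect variance over fixed + random-intercept +
residual variance); for covariate-adjusted models the reported R² always
comes from the effect-only model so that it remains comparable across
rows. Singular fits (a variance component at zero) are flagged in the
result rather than hidden. Covariate families that would overwhelm a small
boundary sample (visual, auditory, layered-feature measures) can first be
compacted to their two leading SVD components each.

The ROI sweep fits the same model per region (bilateral homologs averaged
upstream on z-scored series) and applies Holm–Bonferroni across regions.
Holm controls the family-wise error at the nominal level by construction;
with many nearly-independent regions its realised FWER approaches that
level, so the calibration suite checks the empirical FWER over seeded null
replicates against its binomial sampling bound rather than against the
point value 0.05 (with 40 replicates, an empirical rate slightly above 0.05
is expected half the time even for an exactly calibrated procedure).

## Ordered-event HMM

Multi-voxel patterns are segmented with a left-to-right hidden Markov
model: K event states, each with a Gaussian mean pattern and a shared
isotropic variance, a state sequence that starts in event 1, advances by at
most one state per TR, and must end in event K. K is set to the number of
consensus boundaries (plus one) rather than estimated — data-driven
selection of K is explicitly out of scope. The stay probability is fixed at
1 − (K−1)/(T−1) (K−1 advances expected across T−1 transitions); means and
variance are estimated by EM with an exact constrained forward–backward
E-step, to a relative log-likelihood tolerance of 1e-4 (max 100
iterations). Shift times come from the constrained Viterbi path, which
guarantees exactly K−1 shifts. Per-event variances were rejected for
identifiability at the run lengths involved. The contract for this module
is recovery on synthetic piecewise-constant patterns, not numeric parity
with any external implementation, whose emission conventions differ.

A shift "matches" a boundary when the boundary precedes it by at most
2 TRs (asymmetric, because the neural transition follows the stimulus
change; a symmetric option exists). Peri-shift response curves average the
group time course in epochs around matched and unmatched shifts; the
summary amplitude is the inclusive mean over TR offsets 0–2.

## Greedy data-driven event detection

The data-driven detector asks which time points best explain the group ROI
signal. Starting from a constant-only model it repeatedly adds the
HRF-convolved stick (one candidate per TR) that most reduces the residual
sum of squares, refitting all coefficients jointly (the literal reading of
the constraint that earlier coefficients must not flip sign), subject to:
the new coefficient is positive, no earlier event coefficient changes sign,
and the RSS strictly decreases. Ties (possible on symmetric toys) go to
the earlier TR. The search stops at k events — k is set per run to the
number of consensus boundaries — or earlier if nothing admissible remains,
which is reported, never silently padded. Candidate regressors are built by
the same design code as the hypothesis-driven branch.

## The synthetic-data generator

Every pipeline input can be simulated with known ground truth:

* **Observers**: each detects each boundary independently with that
  boundary's salience probability; presses lag by a reaction time
  (0.9 s + Gaussian jitter, default SD 0.2 s); accidental presses are an
  optional homogeneous Poisson process (default rate 0).
* **BOLD**: HRF-convolved sticks with per-boundary amplitudes, plus cosine
  drift entirely below the 1/256 Hz⁻¹ cutoff (so the high-pass set removes
  it by construction, making filter tests sharp), plus AR(1) noise with a
  stationary SD.
* **Patterns**: piecewise-constant random mean patterns per event plus iid
  noise.
* **Media**: small frames (constant random texture per scene, re-centred so
  frame means equal the scene luminance exactly) and per-scene tone
  mixtures, switching at the cut times; written as PNG/WAV when a directory
  is given. Frames are kept small so the brute-force dense-matrix oracles
  for the image measures run in seconds.

The demo ground truth (`demo_ground_truth()`) is a single 8-minute run with
15 boundaries at irregular 23–34 s intervals, detection probabilities
0.35/0.65/0.95 (low/medium/high salience) and BOLD amplitudes increasing
with salience — the regime the analysis presumes: moderate observer
agreement, a recoverable salience gradient. What the generator does *not*
emulate: head motion, physiological noise structure, spatial correlation
within ROIs, narrative content, or familiarity effects. Passing tests
therefore demonstrate the correctness and calibration of the machinery on
its stated signal model, not performance on real acquisitions.

## Perceptual measures

Visual change uses the spatially weighted image distance and correlation: a
Gaussian proximity matrix G (σ = 1 pixel, as in the measure's source)
truncated to a 9×9 neighborhood, beyond which the weights are numerically
negligible; RGB channels are computed separately and summed. Per-boundary
values take the most-changed cross pair between the 1 s windows before and
after the boundary — distances are maximised and correlations minimised
(the text specifies maximisation for distances only; minimisation is the
symmetric choice for correlations, and it is configurable). Histograms use
256 bins per channel on [0,1]. "Volume" is RMS amplitude over 100 ms
(mean-absolute optional); audio spectra are Hann-windowed periodograms of
500 ms epochs truncated at 5 kHz. The layered feature extractor is a
pluggable interface — any object with `n_layers` and `features(frame)`; the
package ships a deterministic mean-pooling pyramid for tests and demos, and
a pretrained network can be adapted in without touching the analysis code.

## Numerical choices and degenerate inputs

* Constant (zero-variance) series are an error in z-scoring, never silent
  NaNs; constant voxels are dropped (with a warning) before pattern
  segmentation.
* Rank-deficient designs name the collinear columns; a covariate aliased
  with the effect of interest is an error, not a silently dropped column.
* The HMM floors its shared variance at 1e-8 so exactly-noiseless input
  remains numerically stable.
* Boundaries live on a continuous time axis; the TR enters only as a merge
  radius and match window. Within one microtime bin, two boundaries are
  unresolvable and rejected in per-boundary designs.
* All randomness flows from explicit seeds; the pipeline re-seeds from its
  config so a run is reproducible end to end.

## Problem sizes used by the validation suite

The test suite exercises the pipeline at sizes chosen to make the
statistical checks sharp while keeping a full run comfortable on one CPU:
amplitude recovery uses 200 simulated participants (noise SD 0.5), the
mixed-model recovery 100 replicates of 200 participants × 60 boundaries
(slope 0.5), the data-driven recovery 100 participants at unit amplitude
and unit noise, null calibrations 200–300 replicates of 199-permutation tests,
and the family-wise-error sweep 40 replicates of 55 null regions. The demo
pipeline itself (30 participants, 15 true boundaries, 1000 permutations)
runs in a few seconds.

## Known limitations

* The reaction-time correction is a single constant for all observers;
  per-observer reaction times are out of scope.
* The GLM assumes white noise within participant (no prewhitening); the
  permutation null absorbs temporal autocorrelation for the sensitivity
  test, but single-trial betas inherit it as extra variance.
* The match-count permutation test is conservative for sparse event sets
  (see above).
* The HMM's fixed stay probability trades a small amount of flexibility for
  stability at short runs; it is not a likelihood-ratio-grade model of
  event duration.
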