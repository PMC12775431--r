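---
title: "Peri-event ensemble analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-event ensemble analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periens)
```

`periens` implements the analysis chain used to characterise how cortical
neural ensembles encode behavioral events recorded alongside miniscope calcium
imaging or fiber photometry: signal normalisation, peri-event epoch
extraction, permutation-based detection of event-activated neurons,
selectivity classification between two events, pre/post phenotyping around
feeding-bout onsets, linear population decoding with shuffled-label nulls, and
behavioral scores. This vignette explains the models and the choices behind
every tunable parameter; it is the package's design record.

## Signal model and normalisation

Raw fluorescence enters as a neuron × frame matrix with a sampling rate
(`trace_matrix`). Two normalisations are supported, applied in order:

* **ΔF/F** (`compute_dff`): `(F − F0) / F0`, with `F0` the mean baseline
  fluorescence of each neuron. The baseline specification is deliberately
  open: the default is the session-wide mean (appropriate when most of the
  session is quiescent), and a fixed window in session seconds can be supplied
  for recordings with a designated quiet period. Which baseline a photometry
  analysis should use (per-session or per-trial) is a genuine degree of
  freedom; both are expressible here (session `compute_dff`, or per-epoch
  statistics against a local baseline window) and neither is asserted as the
  only correct choice. `F0 ≤ 0` makes the fractional change meaningless and is
  an error naming the neuron rather than a silent NaN.
* **z-scoring** (`zscore_traces`): per neuron over the *full session*, in
  population-SD units (divide by *n*). Per-epoch z-scoring is intentionally
  not offered: re-standardising each epoch would erase amplitude differences
  between events, which are exactly what the downstream activation test and
  selectivity index measure. Zero-SD neurons cannot be standardised and are
  excluded with a warning (and recorded in the result), never silently zeroed.

Time is stored in seconds everywhere; frames are derived via
`frame = floor(t × rate)` and never stored, so 30 Hz imaging, 20 Hz behavioral
video and 100 Hz photometry streams cannot drift apart through integer frame
bookkeeping. All analysis windows are half-open `[t0, t1)` so that abutting
baseline `[-5, 0)` and event `[0, 5)` windows never share a frame.

## Peri-event epochs

`extract_epochs` slices a fixed window around every onset of one label —
by default 10 s before and 10 s after, which at 30 frames per second is
exactly 600 frames with the onset at (0-based) frame 300. Trials whose window
would cross a session edge are dropped, not padded, and the exclusion count
travels with the tensor and into the pipeline manifest; padding would
contaminate window statistics with fabricated samples.

`window_stat` reduces an onset-relative window of each trial to a per-neuron
scalar: mean, max, or the trapezoidal area under the curve in z·s. One
numerical subtlety: a half-open window `[t0, t1)` contains samples spanning
only `(n − 1)` inter-sample intervals, so a literal trapezoid over the
included samples would integrate a 5-s window as 4.967 s at 30 Hz. The AUC
therefore uses the sample sitting at `t1` as the right integration endpoint
whenever it exists inside the epoch (falling back to the available samples at
the epoch edge), so a constant trace of value *c* over a 5-s window yields
exactly 5*c*.

## Event-activated neurons

The detection statistic for each neuron is the trial-mean difference between
its event-window and baseline-window response. The null distribution is built
by **exchanging the baseline/event window labels within each trial**, which
simply flips the sign of that trial's difference; the one-sided p-value is
`(1 + #{null ≥ observed}) / (n_perm + 1)`. The upstream literature names a
permutation test without fixing what is permuted (frames, trials, or window
labels); window-label exchange was chosen because it permutes exactly the
quantity the observed statistic contrasts, assumes nothing about frame-level
autocorrelation (calcium transients are strongly autocorrelated, so
frame-shuffling nulls are anticonservative), and admits an exact version —
with `exact = TRUE` all `2^trials` assignments are enumerated and the p-value
is exact, which the test suite verifies against an independent brute-force
oracle.

A neuron is *activated* only if it passes the permutation test **and** its
mean event-window z-scored response exceeds `z_threshold = 0.2`. The rule is
conjunctive: a response of 0.1 SD units with p = 0.001 is reproducible but too
small to call an activation. Two consequences worth stating:

* The significance level is exposed as `alpha` (default 0.05). The magnitude
  threshold 0.2 is a fixed convention of this analysis style; alpha is an
  assumption and is therefore a visible parameter.
* Because of the conjunction, the *flag rate* on null data is strictly below
  alpha. Type-I calibration of the machinery is therefore assessed with the
  magnitude rule disabled (`z_threshold = -Inf`), where the flag rate must be
  consistent with alpha; with the 0.2 rule active the null rate can only be
  lower. The test suite runs this calibration on 20 null synthetic sessions of
  200 neurons and 20 trials each.

## Selectivity and phase phenotypes

For two events A and B with per-neuron mean responses `A` and `B` (event-window
mean over `[0, 5)`, the same window as the activation test, since the
response period is otherwise unspecified), the selectivity response index is

```
SRI = (A − B) / (A + B)
```

with categories `A_selective` (SRI > 0.2), `B_selective` (SRI < −0.2) and
`shared` otherwise. SRI presumes nonnegative responses; when `A + B ≤ 1e-6`
(including any negative denominator) the ratio loses its `[-1, 1]`
interpretation and the index is reported as `NA`/`undefined` and excluded from
category counts rather than returned as an arbitrary large number.

Pre-cells and post-cells around feeding-bout onset use the same permutation
machinery with shifted windows — pre: baseline `[-10, -5)` vs event `[-5, 0)`;
post: baseline `[-5, 0)` vs event `[0, 5)` — and the per-trial **maximum** as
the window statistic, with the 0.2 threshold applied to the trial-mean
maximum. The two tests run independently; a neuron passing both is assigned to
the phase with the larger event-window maximum, ties to `pre`, keeping the
groups disjoint as they are treated downstream.

Cross-session identity is an external input: `join_registered` consumes a
correspondence table from a spatial-footprint registration tool and
inner-joins per-neuron results, reporting unmatched neurons on both sides.
The registration algorithm itself is out of scope.

## Population decoding

Trials of two events are stacked into an N × M × T tensor (neurons × trials ×
frames) with binary labels. The classifier throughout is a linear
maximum-margin SVM (via `e1071`/libsvm) with cost 1 and class-balanced
weights; features are standardised *inside each training fold only*, so no
test-set statistics leak into the fit. Default features are each neuron's mean
over `[0, 5)` — robust at the trial counts typical of these sessions — with
full N × T flattening available by flag.

* `decode_cv`: stratified k-fold cross-validation (default 10); accuracy is
  the fraction of correctly predicted held-out labels. Fold assignment is
  seed-fixed; if the smaller class has fewer trials than folds the fold count
  drops (minimum 2) with a warning.
* `shuffled_null`: the chance benchmark — permute the label vector, rerun the
  whole CV, repeat. One caveat known from the cross-validation literature and
  visible here: shuffled-label CV accuracy sits very slightly below 0.5
  (typically 0.48–0.50 at M = 40) because training and held-out folds are
  anti-correlated under label permutation. The chance-calibration check
  therefore asks the mean of 50 shuffles to lie inside the binomial 95% band
  for a *single* M-trial decoder, not a band that shrinks with the number of
  shuffles — the latter would measure this well-known pessimism, not decoder
  correctness.
* `decode_timecourse`: at each grid time *t* (default −10 … +9 s, step 0.5 s)
  features are each neuron's mean over `[t, t + 1 s)` and a fresh 5-fold
  decoder is trained, with a shuffled-label control curve; the AUC of the
  accuracy curve over data from 0–10 s after onset summarises post-onset
  decodability.
* `projection_decoder`: the session is split into two *consecutive* halves
  (default 50/50). On the first half a decoder separates population activity
  frames inside labeled events from baseline frames drawn 5 s before each
  event; every frame of the second half is then projected onto the hyperplane
  normal, giving a continuous signed prediction. Frames above the threshold
  (default 0, the hyperplane itself — the upstream "prediction threshold" is
  not quantified anywhere, and the hyperplane is the only canonical choice)
  merge into predicted event intervals; intervals shorter than
  `min_duration = 0.5` s are discarded as single-frame flicker.
  `event_agreement` scores predictions against annotated events by frame-wise
  accuracy, intersection-over-union, and per-event hit rate.

Which neuron subset feeds a decoder is a required explicit argument
everywhere: the conventional choice is the union of activated cells, but
nothing in the mathematics forces it, so the package does not guess.

## The synthetic session generator

Because the recordings this pipeline targets are not publicly deposited, every
stage is validated against `generate_session`, which produces sessions with
known ground truth:

```
trace = baseline_f0 + drift + (spikes ⊗ kernel) + Gaussian noise
```

* **Kernel**: difference of exponentials `exp(−t/τ_decay) − exp(−t/τ_rise)`
  normalised to unit peak, defaults τ_rise = 0.2 s, τ_decay = 1.5 s —
  GCaMP6s-like dynamics.
* **Background activity**: every neuron, responsive or not, emits transients
  at 0.01 spikes/frame, so responsive and non-responsive neurons share
  identical background statistics; group differences can only come from the
  event-locked term.
* **Event-locked responses**: member neurons of an ensemble receive extra
  spikes (3 Hz) inside the ensemble's response window on each trial, with
  Gaussian onset jitter. Spike height is calibrated analytically so that the
  `amplitude` parameter is the target mean elevation over the standard 5-s
  analysis window in units of the noise SD. After full-session z-scoring the
  *realised* elevation is smaller (roughly 50–60% at amplitude 2) because the
  response itself inflates the session SD — a property shared with real
  z-scored calcium data, and the reason detection checks are phrased against
  ground-truth membership rather than against the nominal amplitude.
* **Drift**: a random-phase slow sinusoid plus a normalised random walk,
  default amplitude 5% of baseline fluorescence — large enough to exercise
  ΔF/F and z-score robustness, small enough not to swamp transients. Default
  noise SD is 10% of baseline fluorescence, a realistic single-photon
  miniscope regime.
* **Schedules**: event onsets are drawn uniformly under a minimum-spacing
  constraint by the exact gap construction (draw the free slack, re-insert the
  mandatory gaps). Rejection sampling was rejected: the standard study
  conditions (20 trials at ≥ 21 s spacing in ~560 s) sit near the
  random-parking density where it stalls. Infeasible schedules fail with a
  named error. By default all labels share one timeline (`shared_timeline`) —
  a mouse is in one behavioral event at a time — so epochs of different labels
  are unconfounded; and ensembles are disjoint (`disjoint_ensembles`, one
  membership uniform per neuron partitioned by cumulative fractions), matching
  the selective subpopulations the selectivity and decoding analyses presume.
  Both behaviors can be switched off.
* **Determinism**: every random element flows from one master seed through
  per-neuron derived seeds, so the same configuration is bit-identical and
  adding neurons never changes earlier neurons' traces or the event schedule.

`generate_photometry` produces a single 100 Hz channel whose deterministic
kernel-shaped deflection begins `onset_lag` (default 0.86 s) after each onset
with polarity ±1, emulating negative-going extracellular-ATP sensor responses
or positive-going calcium responses. `generate_behavior` draws place-preference
occupancy (proportion `paired_bias` ± noise over a 20-min test), context
intake, and feeding-bout tables.

**What the generator does not emulate** — and hence what passing tests do not
certify about real recordings: source-extraction artefacts (crosstalk between
neighbouring ROIs, neuropil contamination), photobleaching trends beyond the
slow drift term, motion, non-Poisson burst statistics, and correlated
population noise. Conclusions about the pipeline's statistical calibration
and recovery transfer to real data only to the extent that real noise
resembles this model.

## Numerical and degenerate-input conventions

* Population SD (divide by n) everywhere a SD is computed on traces.
* `frame = floor(t × rate)` maps times to frames; windows half-open.
* Onset latency: first sample after the baseline window beyond baseline mean
  ± 2 SD, upward or downward. With per-sample noise this first-crossing rule
  fires early by chance (each gap sample has ~2.3% probability of breaching a
  2-SD band), which is a property of the rule itself; deterministic recovery
  to one sample period is therefore verified on noiseless constructed
  deflections, and noisy use is expected on trial-averaged traces.
* Degenerate inputs error loudly and name the offender: nonpositive F0,
  zero-SD baselines, overlapping test windows, fewer than 2 trials, single-class
  label vectors, empty accuracy lists, missing bout offsets, occupancy
  summing to zero.
* Overlapping annotated bouts are merged (union) with a warning — real
  annotation files contain overlaps, and rejecting them would make the
  summary unusable.
* Tensor/decoder randomness (fold assignment, shuffles, permutations) is
  seed-fixed through derived child seeds, making every pipeline output
  reproducible from the manifest.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic sessions
chosen to finish comfortably on one CPU: calibration uses 20 (suite) or 10
(script) null sessions of 200 neurons × 20 trials; recovery and selectivity
use 200-neuron sessions at amplitude 2; decoding uses two-event sessions of
150–200 neurons with 20 trials per event; the projection decoder uses an
80-neuron session with 16 six-second bouts over 800 s. The full suite runs in
roughly a minute; `scripts/acceptance.R` in under a minute.

## Limitations

* The pipeline consumes extracted traces; motion correction, source
  extraction, spike deconvolution and photobleaching correction are upstream
  and out of scope, as is the cross-session registration algorithm.
* Binary decoding only; no multiclass, nonlinear, or recurrent decoders.
* The permutation scheme and alpha are documented package decisions where the
  upstream description is silent; both are recorded in every result object so
  downstream reports can state them.
* Correlation p-values are uncorrected; multiple-testing control is the
  caller's responsibility.
* Trace I/O is plain-text CSV/TSV/JSON; values round-trip to better than
  1e-12 relative error.
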