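---
title: "Methods: RT-coupled GLM and lagged BOLD-behavior cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RT-coupled GLM and lagged BOLD-behavior cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvigil)
```

# Scope and rationale

`boldvigil` analyzes sustained-attention ("vigilance") task fMRI in which
the behavioral readout is the trial-by-trial reaction time (RT). Slow
fluctuations of the attentional state should express themselves both in RT
and in brain activity, and — critically — activity reflecting the state
should be informative *before* the response is given. The package
therefore pairs a conventional RT-modulated GLM (which assumes the
canonical hemodynamic lag) with a lagged cross-correlation that makes no
assumption about the temporal relationship, scanning lags of −50 to +50 s.

Because no subject data are distributed with the package, the synthetic
module is a first-class citizen: it generates cohorts whose statistical
structure matches what the analyses assume, with known coupling sign,
amplitude and temporal lead per voxel, so both analyses are validated by
parameter recovery rather than by comparison with irreproducible
real-data values.

# The task model

The paradigm is a grid-based continuous-performance task. Each trial shows
a triangle and a polygon in two distinct cells of a 4 × 4 grid, drawn in
one of six colors. Ongoing (OG) trials require a left/right judgment of
the polygon relative to the triangle; when the two cells are a chess
knight's move apart — displacement (1,2) or (2,1) — the trial is a
prospective-memory (PM) trial requiring a different button. Defaults:
204 trials at a 3-s onset asynchrony (stimulus 0.5 s), 20 PM trials
(9.8%), at least 4 OG trials between PM trials, first 4 trials OG. Trial
*i* (1-based) onsets at 3·*i* s so the run spans 612 s = 306 volumes at
TR 2 s, and every second trial onset coincides with a volume acquisition.

Three design choices were genuinely open:

* **PM placement.** The constraint set (20 positions among trials 5…204
  with inter-PM gaps ≥ 4) admits a classical stars-and-bars bijection to
  unconstrained 20-subsets of a shorter index range, so PM positions are
  sampled *exactly uniformly* over the feasible set in O(n). Whole-vector
  rejection sampling has an acceptance probability of roughly 5·10⁻⁵ at
  these defaults and was rejected as an implementation.
* **Same-column OG stimuli.** The left/right judgment is undefined when
  both shapes share a column; OG stimuli are constrained to differ in
  column so every trial has a well-defined correct response.
* **Distance classes.** The 4 × 4 grid yields 9 distinct inter-cell
  Euclidean distances (squared distances 1, 2, 4, 5, 8, 9, 10, 13, 18).
  Removing the knight-move distance √5 leaves exactly 8 classes, which is
  why the stimulus-similarity analysis is read as operating on distance
  classes (8 of them) rather than on raw displacement pairs.

# The synthetic-data generator

**Latent vigilance.** A stationary AR(1) process on trials,
x_t = φ x_{t−1} + ε_t, with φ = 0.9 and unit innovation SD by default.
At a 3-s trial spacing the autocorrelation time is 3/−ln(0.9) ≈ 28 s,
i.e. the latent state fluctuates over tens of seconds — the regime in
which a lagged analysis is informative at all. AR(1) on trials is the
simplest process with this property; nothing downstream depends on the
specific process family.

**Reaction times.** RT = 816 ms (+ 134 ms on PM trials) + 100 ms × latent
+ trial noise (SD 80 ms), floored at 150 ms and capped just below the next
onset (responses are valid until the next stimulus). Accuracy is Bernoulli
(97% OG, 69% PM). The location/penalty/accuracy values are calibrated to
the behavioral regime of the study the paradigm comes from; the latent
gain and noise SD are the generator's own choices, set so that within-run
RT variability (≈ 240 ms SD) is realistic for a speeded judgment task.

**BOLD.** Per voxel: baseline 100 + task response (onset sticks ⊗ HRF ×
task amplitude, default 1% — half of the positively modulated voxels get a
*negative* task response so the deactivation/modulation overlap structure
exists in the ground truth) + coupling (standardized-RT-weighted sticks,
shifted *earlier* by `lead_s`, ⊗ HRF × signed amplitude, default 0.5% per
SD of RT) + linear drift (0.2%/min) + Gaussian noise (SD 1%). The lead
implementation — shifting the modulated stick function before convolution
— models anticipatory activity without inventing a second HRF shape.
`lead_s` defaults to 0 (task-locked coupling); the timing-recovery
experiments set the negative network's lead to 10 s. Noise is temporally
white by default; an AR(1) noise option exists because real BOLD noise is
autocorrelated and no analysis stage is allowed to depend on whiteness.

What the generator does *not* emulate: anatomy and spatial correlation,
physiological (cardiac/respiratory) noise, motion-induced signal change,
susceptibility artifacts, nonlinear HRF effects. Passing recovery tests
therefore demonstrates the correctness of the analysis machinery under
the stated model, not robustness to every property of real data.

# The parametric GLM

Regressors are built at 0.1-s microtime resolution and sampled at volume
times (no slice-timing offset exists in synthetic data). The canonical
HRF is the standard double-gamma difference (delays 6/16 s, unit
dispersions, peak:undershoot 6, 32-s support), peak-normalized; its mode
is ≈ 5 s. Each occurring condition contributes an onset regressor and a
parametric regressor whose stick weights are that condition's mean-
centered RTs (mean-centering per condition per run; trials without a
response carry no parametric stick). Six motion parameters pass through
unmodified. High-pass filtering is implemented by *including* the
discrete-cosine basis (periods > 128 s; 10 columns at 306 volumes,
constant included) in the design — an equivalent projection to
pre-filtering, with cleaner provenance. With all four conditions present
this yields the canonical 14 task + motion regressors.

Empty conditions and degenerate (constant-RT) parametric columns are
dropped and recorded. Rank-deficient designs abort, naming the collinear
columns. Runs are fit separately by OLS and condition betas averaged per
subject; group maps are voxelwise one-sample t-tests (df = subjects − 1)
with Bonferroni correction over analysis-mask voxels — chosen over
random-field-theory FWE deliberately: it is conservative, assumption-free
and exactly reproducible on small synthetic grids.

# The lagged cross-correlation

Per run and voxel: linear detrend; build the behavioral series from
correct OG trials only (PM and incorrect trials are never sample points
but are interpolated across); evaluate the piecewise-linear interpolant
of (onset, RT) on a 1-s grid; then for each lag τ ∈ {−50, …, +50} s
correlate BOLD at volume times *t* with behavior at *t* − τ over the
overlap of valid samples. Fisher-Z (atanh) transform, average across
runs. Negative τ means the brain signal precedes the behavior.

Numerical and design choices:

* **Lag step vs TR.** Lags step by 1 s while volumes arrive every 2 s.
  The behavioral series is evaluated on a 1-s grid (its interpolant is
  closed-form at any time) and paired with unresampled volumes — the BOLD
  signal is never interpolated.
* **Interpolation reading.** "Interpolate RTs to the matching volume" is
  implemented as evaluation of the linear interpolant at volume times;
  assignment to the nearest following volume is available as the
  documented `nearest_volume` option.
* **Gaps.** Runs of PM/incorrect trials leave gaps between usable sample
  points; gaps are bridged by the interpolant up to `max_gap_s` (default
  15 s ≈ four missing trials), beyond which grid points are invalid.
* **Overlap.** Sample count varies with lag (the shifted series slides
  out of the run); a lag needs ≥ 10 valid pairs per run, otherwise it is
  missing for that run and run-averaging uses the available runs. Z
  values are not reweighted by sample count, matching plain averaging.
* **Degenerate correlations.** r is clamped to ±(1 − 10⁻⁶) before atanh,
  so perfectly collinear synthetic inputs give a large finite Z instead
  of infinity; zero-variance behavioral segments mark the lag missing.
* **Group model.** Windows of 5 consecutive lags are averaged per subject
  (window labeled by its mean lag: lags 1–5 s → 3 s) and tested with
  one-sample t-tests — equivalent to the time-factor ANOVA contrast usage
  they replace — Bonferroni-corrected over voxels × pre-stimulus windows
  (5 windows at family level 0.05 → 0.01 per window).
* **Controls.** The common-timepoint control uses only coincident
  volume/trial times (every 6 s; at most 102 per run) with no
  interpolation; log(RT) and |RT − run mean| transforms are available as
  drop-in behavioral series.
* **ROI onsets.** ROI masks (e.g. the GLM's positive/negative modulation
  maps) are averaged per subject and lag; the onset of significance is
  the most negative lag from which p stays below threshold (default
  0.0005 = 0.05 / (2 masks × 50 pre-stimulus lags)) at every lag through
  stimulus onset. Masks derived from the GLM bias the profile toward a
  peak near +5 s, so only the *relative* ordering of two networks'
  onsets is interpreted — absolute onset times are inflated by the
  autocorrelation of both the latent process and the HRF.

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the
lagged correlation against a brute-force shift-and-correlate loop with
the textbook Pearson formula (agreement to 10⁻¹⁰), OLS against an
explicit normal-equations solve (10⁻⁸), the trial sequencer against an
independent constraint checker, and the behavioral summaries against
brute-force recounts of the raw event tables.

Recovery and calibration experiments use sizes chosen for desk-scale
runtimes while keeping the relevant statistics meaningful: sign recovery
and lag-similarity on one 12 × 12 × 8-voxel cohort (24 + 24 modulated
voxels, 21 subjects × 2 runs); the negative-before-positive onset
ordering on 20 cohorts of 21 subjects × 2 runs over a minimal 8-voxel
grid (the ROI analysis only reads the modulated voxels, so simulating a
large null background would add runtime without adding information);
null calibration on a 1,152-voxel zero-coupling cohort and 1,000
pure-noise voxels. The interpolated-vs-common-timepoint concordance is
asserted on the modulated voxels: where a voxel has no coupling, both
profiles are near-zero noise vectors and their correlation measures
nothing about method agreement.

# Known limitations

* Spatial structure is absent from the generator, so spatial smoothing,
  cluster inference and anatomical labeling are out of scope; Bonferroni
  correction is exact but conservative for spatially smooth real data.
* GLM residuals are not prewhitened; with the default white-noise
  generator OLS is efficient, and the AR(1)-noise option exists precisely
  to check that conclusions do not hinge on whiteness.
* The behavioral interpolant bridges short gaps; with very low accuracy
  or many PM trials the usable series fragments and lags start dropping
  below the overlap minimum.
* Absolute onset-of-significance times are systematically early (latent
  and hemodynamic autocorrelation); the package reports them but the
  supported inference is the comparison between networks.
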