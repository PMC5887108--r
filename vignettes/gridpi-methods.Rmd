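---
title: "Hexadirectional grid-code analysis and path-integration scoring: methods"
author: "gridpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hexadirectional grid-code analysis and path-integration scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpi)
```

## The scientific problem

Grid cells in entorhinal cortex fire on a hexagonal spatial lattice.
In fMRI their population signature is a *hexadirectional* (6-fold
symmetric) modulation of the BOLD signal by the direction of
translational movement through an environment: voxels respond more
strongly when movement is aligned with the (voxel-specific) grid
orientation, with a 60°-periodic profile `cos(6(α − φ))` in movement
direction α. `gridpi` implements the standard split-half,
quadrature-regressor estimation of this effect, the stability metrics
used to interrogate it, and the scoring of a multi-stop
path-integration task whose performance the grid signal is
hypothesized to support — together with a synthetic-data generator that
plants all of these effects with known ground truth, so that every
stage of the analysis can be validated by parameter recovery.

## The grid-code model and its estimation

For each scanning run the data are split at the temporal midpoint.
An event belongs to the half containing its onset; onsets exactly at
the midpoint go to the second half.

**GLM1 (estimation).** On the first halves, translation events are
modeled as boxcars convolved with the canonical double-gamma HRF
(response peak 6 s, undershoot 16 s, amplitude ratio 6, no
derivatives), with two parametric modulators per event, `sin(6α)` and
`cos(6α)`. Modulator weights are mean-centered across the modeled
events before convolution, so the translation main effect absorbs the
offset; no further orthogonalization is applied. Per voxel v the fitted
coefficients (β₁ for sine, β₂ for cosine) give the voxel orientation

> φ_v = atan2(β₁, β₂) / 6, mapped into [0°, 60°),

and the ROI mean orientation φ is computed from the ROI-*averaged*
betas — average first, then atan2 — never by averaging voxel
orientations (the printed ratio-arctangent form loses the quadrant;
the four-quadrant atan2 is the standard reading and is what the
quadrant oracle in the test suite checks exhaustively).

**GLM2 (test).** On the second halves a single *aligned* modulator
`cos(6(α − φ))` is built from the estimation-half φ. The
cross-validated **magnitude** of the grid-cell-like representation is
the ROI mean of its fitted coefficient. By construction the expected
magnitude is proportional to `cos(6Δφ)` where Δφ is the true
orientation change between halves: positive below 15°, zero at 15°,
minimal at the maximal detectable change of 30°. The package
reproduces this sign law on noiseless planted data to r > 0.999.

**Nuisance model.** Every GLM includes the six head-motion parameters,
the *unused* half's translation events as an unmodulated boxcar (their
modulators are deliberately omitted to keep GLM1/GLM2 estimable), the
feedback phase, and one intercept per run. Translation events shorter
than 1 s (strict inequality; a 1.0 s event is retained) are not
modeled at all. GLM2 is fit jointly over all test halves with per-run
intercepts; a per-run fit with averaged magnitudes is available as a
flag. HRF temporal derivatives and prewhitening are off by default and
exposed only through the noise options of the generator — the package
makes no fidelity claim about them.

**Controls.** The same machinery runs with 5- and 7-fold symmetry
(orientation domains [0°, 72°) and [0°, 51.4°)); only the 6-fold model
should detect planted 6-fold modulation. Data-reduction controls
implement the two modes used to equate data amounts between groups:
truncating runs (drop trailing events until retained translation time
is at most the requested fraction of the original — closest from
below, whole events only) and truncating translations (each duration
multiplied by the fraction, onsets unchanged), with 0.8016 as the
shipped fraction. Signal quality is summarized by voxel-wise tSNR
(temporal mean over temporal SD, ROI-averaged, zero-SD voxels excluded
with a warning) and by framewise |Δx|+|Δy|+|Δz| and
|Δyaw|+|Δpitch|+|Δroll| motion summaries.

## Stability metrics

Voxel orientations are estimated separately for each half of each run.
A voxel is **temporally stable** if its orientation differs by at most
15° (inclusive — the boundary is measure-zero but a convention is
needed) on the 60°-periodic domain; the score is the proportion of
stable voxels averaged across runs. Under independent uniform
orientations the circular difference is uniform on [0°, 30°], so the
chance level is exactly 0.5 and the expected mean absolute change is
15° — both reproduced by simulation in the acceptance suite. **Spatial
stability** is Rayleigh's z = nR² of the voxel orientations after
multiplying by 6 to map the 60°-domain onto the full circle (without
this mapping a circular test on periodic orientations is meaningless);
the p value uses the Wilkie/Zar small-sample series. Whether the
original analysis pooled orientations across runs or averaged per-run
z values is not stated anywhere we could verify; the default here is
per-run z values averaged across runs, with a pooled variant exposed.

## Path-integration task and scoring

Eight curved paths are built from 3-legged templates: leg lengths from
{2, 3, 4, 5} m, two signed turns from ±{55°, 80°, 105°}, dead-reckoned
into four waypoints, then interpolated by a natural cubic spline
through the waypoints with centripetal (square-root chord length)
parameterization — the convention of the MATLAB `cscvn` routine this
construction emulates; a chordal flag exists for comparison. The three
stopping points sit on the curve at the first turn, the second turn
and the path end (the most natural reading of a three-stop design;
configurable). Every curve must fit a 10 × 6 m room. The shipped
templates are turn-direction counterbalanced (two of each left/left,
left/right, right/left, right/right pattern) and are *not* the
original study's combinations, which are only printed in a supplement
unavailable here; they are clearly labeled synthetic stand-ins drawn
from the same menus under the same constraints.

A session is 32 traversals (8 paths × 2 repetitions × 2 modalities,
16 per modality) in two blocks of 16, pseudo-randomized under the
constraint that two occurrences of the same path are separated by at
least three different intervening paths; a fixed default seed ships so
every synthetic participant walks the same order. In the middle of
each block sit four straight standardization paths in the fixed order
9m-visual, 3m-body-based, 9m-body-based, 3m-visual.

**Scoring.** Responses of the same standardization distance and
modality are averaged and converted to correction factors
f = d_correct / d_response (ratio of the true distance to the *mean*
response — the printed order of operations, not a mean of ratios).
Raw responses up to and including 6 m are multiplied by the 3 m
factor, responses above 6 m by the 9 m factor (the boundary belongs to
the short factor: "between 0 and 6 m"). At stop k the standardized
distance and responded bearing give the presumed starting point
`presumed_k = stop_k + d_std · (cos θ, sin θ)`; the incremental error
at stop k is ‖presumed_k − presumed_{k−1}‖ with presumed₀ the true
start. Errors are averaged over all stops of a modality;
performance = 1/error, reported as NA when the mean error is 0.
Bearings are absolute directions in the arena frame (degrees
counterclockwise from +x); device conversions are the caller's job.

Because the 6 m branch is decided on the *raw* response, a global
rescaling of all responses is exactly cancelled by the correction
whenever the factor pair is itself a pure scale (as for a verbal-scale
agent) or no response crosses the 6 m boundary; the test suite asserts
both the exact cancellation for pure verbal-scale agents — the stated
purpose of the standardization — and the branch-stable noisy case.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed
once and used by all validation experiments.

**Navigation sessions.** Four runs of 960 s (TR 1.5 s → 640 scans per
run) of an object-location task in a 160 × 160 vm square arena:
cue (2 s) → navigate (alternating rotations at 50 deg/s and straight
translations at 15 vm/s — the two never overlap) → confirmation pause
→ feedback (1.5 s) → teleport to a random position (no translation
event). Three target objects are drawn centrally with their centroid
recentred on the arena midpoint, which keeps translation directions
near-isotropic (mean resultant length well below 0.1 over a session) —
a deliberate generator choice, since the directional GLMs assume
reasonable direction coverage. Translation segments have a 16 vm
minimum (≥ 1.07 s at 15 vm/s), so simulated sessions contain no
sub-second translations; the < 1 s exclusion rule is exercised by
hand-crafted event tables in the unit tests. Trial counts and
inter-trial timing are not printed anywhere we could verify; the
defaults above yield roughly 45–60 trials and ~100 translation events
per 16-minute run and are configurable, not inferred.

**BOLD forward model.** Per voxel: baseline 100, a translation main
effect, and an impulse train at translation events with height
`amplitude · cos(6(α − φ_v))`, convolved with the same canonical HRF
and the same 0.25 s high-resolution grid as the analysis design
matrices (one shared primitive — so planted signals lie exactly in the
span of the noiseless design, and orientation recovery is exact to
machine precision), plus i.i.d. Gaussian noise (optional AR(1)),
random-walk motion parameters and an optional motion-correlated
artifact. Voxel orientations scatter around a participant-level φ with
5° wrapped-Gaussian spread, mimicking within-ROI spatial coherence.
**Drift** (the old-age mechanism): at each half-run boundary a voxel's
orientation is redrawn uniformly with probability `p_drift` and always
jittered by a small Gaussian — the simplest mechanism that reproduces
chance-level temporal stability at `p_drift = 1` (planted stability
≈ 1 − p_drift/2 between the halves of a run). The orientations actually
in force per half-run are returned as ground truth.

**Agents.** Responded distance = true distance × path-integration gain
× verbal scale × mean-one lognormal noise (CV parameter); responded
bearing = true bearing + von Mises noise (concentration κ).
Standardization walks carry the verbal scale and distance noise but
not the gain — the verbal component is exactly what the correction is
designed to remove.

**Cohort.** 20 young and 21 older participants. Young: amplitude
~ N(1.0, 0.3) truncated at 0.2, `p_drift` 0.05, agent noise drawn
independently of the grid signal. Old: amplitude ~ N(0.45, 0.3)
truncated at 0.05, `p_drift` 0.5, and — the planted brain–behavior
coupling — heading concentration and distance CV tied log-linearly to
the participant's amplitude, so lower grid signal means noisier path
integration. One older participant's neuropsychological scores are set
missing, matching the study's documented partial case, and is handled
by per-analysis column subsets. The ROI size (30 voxels) is a
realistic partial-volume entorhinal ROI; no voxel count is printed
anywhere we could verify, so it is a package default, not an inferred
value.

What the generator does *not* emulate: physiological noise and
scanner drift, susceptibility distortion, spatial smoothing (analysis
is ROI-restricted from the start), inhomogeneous within-ROI amplitude
maps, realistic trial-difficulty structure, or learning effects in the
path-integration task. Passing tests therefore demonstrate that the
*analysis code* measures what it claims on data generated by its
stated forward model — not that the forward model exhausts real fMRI
or behavioral variability.

## Statistics

Group tests are plain t statistics (pooled-variance Student two-sample
tests by default, df = n₁ + n₂ − 2, matching the reported t₃₉-style
degrees of freedom; Welch available), two-sided, threshold 0.05, no
multiple-testing correction. The covariate-adjusted group effect is a
homogeneous-slopes ANCOVA whose F equals the squared t of the group
coefficient in the joint linear model — asserted to 1e-8 in the tests.
The regression table is raw-scale OLS (a z-scoring flag exists; the
magnitudes of published coefficients suggest raw scale, and raw is the
default) with listwise deletion. Subgrouping uses 3-cluster k-means on
the scalar magnitudes with deterministic centroid seeds — the means of
the 6 lowest, 6 middle (central ranks ⌈n/2⌉−2 … ⌈n/2⌉+3) and 6 highest
values. The median split assigns values *strictly below* the median to
the low-error group (for odd n the median is a data point; with 21
older adults this yields the documented 10-member low-error group; for
even n the rule coincides with a plain below/above split; full ties go
to high-error).

## Numerical choices and degenerate inputs

* Convolution runs on a 0.25 s grid with FFT padding to a power of two
  and a cached kernel transform; boxcars are sampled at scan times
  (i − 1)·TR.
* Designed experiments (the sign-law sweep, exact-recovery checks) use
  a deterministic event table with an 80 s silent gap bracketing the
  run midpoint, so no HRF response from estimation-half events leaks
  into test-half scans; this makes the zero crossing of the sign law
  analytically clean. Stochastic experiments use the navigation
  simulator, where the small cross-half HRF spillover is part of the
  measured conditions (its effect on the magnitude is < 1%).
* Rank-deficient designs abort with the names of the collinear
  columns; runs lacking translation events in one half are excluded
  from orientation averaging with a warning; a voxel with zero
  temporal SD is excluded from tSNR with a warning; `orientation
  undefined` is raised when both mean betas are exactly zero;
  performance is NA (never Inf) at zero error.
* All randomness flows through explicit seeds (child seeds derived
  below 2³¹); identical seeds give byte-identical outputs, which the
  pipeline verifies by manifest hashing.

## Problem sizes used by the validation suite

Chance-level stability: 500 voxels × 1000 replicates. Sign law: 61
values of Δφ at 0.5° steps, one noiseless voxel. Orientation recovery:
100 orientations planted as 100 voxels of one two-run session. Fold
specificity: 50 sessions at the study's full session size (4 × 960 s,
12 voxels, amplitude 0.5, noise SD 1). End-to-end pattern: 100
replicates of the full default cohort (grid magnitudes and
path-integration scoring per replicate; the stability metrics, which
do not enter the tested pattern, are computed in the single-replicate
checks). These sizes are the package's choices for a reproducible
desk-scale validation; all are arguments, not constants.

## Known limitations

The generator's BOLD model is linear and stationary; no attempt is
made to emulate field-strength- or age-dependent hemodynamics, so
group differences in the synthetic cohort are purely neural by
construction. The quadrature estimator inherits the usual small-sample
crosstalk between symmetry folds (mismatched-fold magnitudes are
unbiased only asymptotically in the number of events; at full session
size the residual bias is well below the Monte-Carlo error, which is
why the fold-specificity experiment uses full-size sessions). The
spline construction matches `cscvn` up to parameterization convention.
In the synthetic cohort the old group's spatial stability (Rayleigh z)
is also reduced — a side effect of orientation drift and lower
amplitude making voxel estimates noisier — whereas the real study
found no group difference on that metric; the generator plants no
*separate* spatial-instability mechanism, so this metric should not be
read as emulated.
exact curve shapes differ from the originals since the original
templates are not available. Real response devices (HMD gyrometer,
joystick) are out of scope: bearings enter in the arena frame.
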