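# gridpi

Cross-validated **hexadirectional (grid-cell-like) fMRI analysis** and
**multi-stop path-integration scoring**, with a synthetic-data
generator that makes every stage verifiable by parameter recovery.

Grid cells in entorhinal cortex fire on a hexagonal lattice; in fMRI
their population signature is a 6-fold symmetric modulation of the
BOLD signal by translation direction α, with profile `cos(6(α − φ))`
around a voxel's grid orientation φ (60°-periodic). `gridpi` is aimed
at researchers in spatial cognition and cognitive aging who want the
standard split-half quadrature estimator of this effect — and its
stability metrics and behavioral counterpart — as tested, scriptable R
functions:

* **Grid analysis** — split each run at its temporal midpoint;
  estimate voxel orientations on the first halves from the quadrature
  modulators `sin(6α)`, `cos(6α)` (GLM1), with the mean orientation
  `φ = atan2(mean β₁, mean β₂)/6` on `[0°, 60°)`; quantify the
  cross-validated magnitude on the second halves as the ROI-mean
  coefficient of the aligned modulator `cos(6(α − φ))` (GLM2).
  Expected magnitude ∝ `cos(6Δφ)` in the half-to-half orientation
  change: positive below 15°, negative beyond, minimal at 30°.
  5-/7-fold controls, 80.16% data-reduction controls, tSNR and
  framewise head-motion summaries included.
* **Stability metrics** — temporal stability (fraction of voxels
  within ±15° between halves; chance 0.5), mean absolute orientation
  change (chance 15°), and spatial stability (Rayleigh z after mapping
  the 60° domain onto the full circle).
* **Path integration** — eight spline-curved paths (legs {2,3,4,5} m,
  turns ±{55,80,105}°, natural interpolating cubic spline, 10 × 6 m
  room), a 32-traversal session design with mid-block standardization
  paths, verbal-distance correction `f = d_correct/d_response` with
  the 6 m short/long threshold, and incremental presumed-start errors
  (`presumed_k = stop_k + d_std·(cos θ, sin θ)`), aggregated to
  per-modality error and performance = 1/error.
* **Synthetic data** — navigation sessions in a 160×160 vm arena
  (15 vm/s, 50 deg/s), grid-modulated BOLD with planted orientations
  and half-run orientation drift (the "old-age" mechanism), noisy
  path-integration agents (gain, verbal scale, lognormal distance
  noise, von Mises heading noise), and a 20-young/21-old cohort whose
  old group couples agent noise to grid amplitude.
* **Group statistics** — pooled-variance t tests, ANCOVA (≡ group
  coefficient in the joint linear model), the raw-scale multiple
  regression table, seeded 3-cluster k-means subgrouping, and the
  median split.

## Worked example

```r
library(gridpi)

# simulate one participant: 2 runs of 8 min, 20 voxels at phi = 23
ev   <- simulate_navigation_session(arena_config(), n_runs = 2,
                                    run_duration = 480, seed = 1)
pg   <- planted_grid(n_voxels = 20, phi = 23, spatial_sd = 0,
                     amplitude = 1, noise_sd = 1, seed = 5)
bold <- generate_bold(ev, pg, tr = 1.5, seed = 2)

gr <- crossval_grid_magnitude(bold, ev)
gr$phi        # 23.003 -- planted 23, recovered from the noisy data
gr$magnitude  # 1.0012 -- planted amplitude 1

st <- stability_summary(bold, ev)
st$temporal_stability  # 1 (no drift planted)

# path integration: a verbally-biased but otherwise perfect agent
paths <- default_path_set()
des   <- build_session(paths)
rec   <- simulate_pi_responses(paths, agent_profile(verbal_scale = 2),
                               "body_based", seed = 1, session = des)
score_pi_records(rec, paths)$body_based$mean_error
# 1.3e-15 -- the 3 m / 9 m standardization cancels the verbal bias exactly
```

The numbered drivers under `analysis/` run the whole synthetic study
(`Rscript analysis/01_simulate.R 1`, then `02_grid_analysis.R` …
`06_validation.R`) and write their tables under `results/`. With the
default seed the cohort reproduces the qualitative result pattern of
the aging study the generator emulates:

```
mean 6-fold magnitude by group:   old 0.081, young 0.724   (t39 = -12.6)
5-/7-fold control magnitudes:     |mean| < 0.01, n.s.
temporal stability:               old 0.753, young 0.978   (chance 0.5)
PI error (body-based, m):         old 2.05,  young 1.09    (t39 = 3.02)
old-group r(magnitude, error):    -0.88     young-group r: 0.02
regression on old-group PI performance: only grid magnitude significant
median split of older adults:     10 low-error / 11 high-error
```

`run_pipeline(pipeline_config(...))` composes the same stages into one
deterministic bundle with per-artifact provenance (config hash) and an
MD5 manifest; rerunning the same configuration reproduces identical
manifests.

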