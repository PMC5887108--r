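#' Designed event table for planted-orientation experiments
#'
#' A deterministic single-run event stream built for clean split-half
#' experiments: equally spaced translation directions, constant event
#' durations, and a silent gap bracketing the run's temporal midpoint
#' so that no HRF response from estimation-half events can leak into
#' test-half scans (causal separation of the halves).
#'
#' @param n_per_half translation events per half.
#' @param event_duration translation duration in seconds.
#' @param isi inter-event interval in seconds.
#' @param gap silent interval (s) centered on the run midpoint.
#' @param direction_offset added to all directions (degrees).
#' @return an `event_table` with one run.
#' @export
designed_event_table <- function(n_per_half = 120, event_duration = 2,
                                 isi = 2, gap = 80,
                                 direction_offset = 0) {
  step <- event_duration + isi
  half_span <- n_per_half * step
  duration <- 2 * half_span + gap
  # interleave directions so each half samples the circle evenly
  dirs <- wrap_deg(seq(0, 360, length.out = n_per_half + 1)[-1] +
                     direction_offset)
  ord <- order((seq_len(n_per_half) * 7) %% n_per_half)
  onsets1 <- (seq_len(n_per_half) - 1) * step
  onsets2 <- half_span + gap + onsets1
  df <- data.frame(run_id = 1L, trial_id = seq_len(2 * n_per_half),
                   onset = c(onsets1, onsets2),
                   duration = event_duration, kind = "translation",
                   direction = c(dirs[ord], dirs[rev(ord)]))
  make_event_table(df, c(`1` = duration))
}

#' Cross-validated magnitude as a function of imposed orientation change
#'
#' Plants noiseless n-fold modulation with orientation `phi` in the
#' estimation half and `phi + delta` in the test half of a designed
#' session, runs the full split-half pipeline at each `delta`, and
#' returns the measured magnitude. The expected curve is
#' `amplitude * cos(n_fold * delta)`: positive below a quarter period
#' (15 degrees for n = 6), zero at it, minimal at the half period
#' (30 degrees).
#'
#' @param deltas imposed orientation changes in degrees.
#' @param phi planted estimation-half orientation (degrees).
#' @param amplitude planted modulation amplitude.
#' @param n_fold directional symmetry.
#' @param events a designed `event_table` (default
#'   [designed_event_table()]).
#' @return data.frame with `delta` and `magnitude`.
#' @export
magnitude_vs_orientation_change <- function(deltas, phi = 20,
                                            amplitude = 1, n_fold = 6,
                                            events = designed_event_table()) {
  period <- 360 / n_fold
  pg <- planted_grid(n_voxels = 1, phi = phi, spatial_sd = 0,
                     amplitude = amplitude, noise_sd = 0, n_fold = n_fold)
  cache <- new.env(parent = emptyenv())
  mag <- vapply(deltas, function(d) {
    seg <- matrix(c(phi, wrap_deg(phi + d, period)), 1)
    bold <- generate_bold(events, pg, tr = 1.5, seed = 1,
                          phi_segments = seg, motion_sd = 0)
    crossval_grid_magnitude(bold, events, n_fold = n_fold,
                            cache = cache)$magnitude
  }, 0)
  data.frame(delta = deltas, magnitude = mag)
}

#' Zero crossing of the magnitude-versus-orientation-change curve
#'
#' Sweeps the imposed half-to-half orientation change over `[0, 30]`
#' degrees on a noiseless planted session and locates the change at
#' which the cross-validated magnitude switches sign, by linear
#' interpolation between the bracketing grid points.
#'
#' @param step sweep step in degrees.
#' @param ... passed to [magnitude_vs_orientation_change()].
#' @return list with `crossing` (degrees), `argmin` (degrees), `curve`
#'   (the sweep data.frame) and `cos_r` (correlation with
#'   `cos(6 delta)`).
#' @export
sign_boundary_experiment <- function(step = 0.5, ...) {
  sw <- magnitude_vs_orientation_change(seq(0, 30, by = step), ...)
  i <- which(diff(sign(sw$magnitude)) < 0)[1]
  if (is.na(i)) stop("no sign change found in [0, 30]")
  m1 <- sw$magnitude[i]; m2 <- sw$magnitude[i + 1]
  crossing <- sw$delta[i] + step * m1 / (m1 - m2)
  list(crossing = crossing, argmin = sw$delta[which.min(sw$magnitude)],
       curve = sw,
       cos_r = stats::cor(sw$magnitude, cos(6 * sw$delta * pi / 180)))
}

#' Chance-level temporal stability under uniform orientation maps
#'
#' Draws pairs of independent uniform voxel-orientation maps and
#' averages the proportion of "stable" voxels (within +/-15 degrees on
#' the 60-degree domain) across replicates. The expectation is exactly
#' 0.5 — the chance level of the temporal-stability score.
#'
#' @param n_voxels voxels per map.
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param n_fold directional symmetry.
#' @return list with `mean_stability`, `mean_change` (degrees) and the
#'   per-replicate vectors.
#' @export
chance_stability_experiment <- function(n_voxels = 500, reps = 1000,
                                        seed = 1, n_fold = 6) {
  period <- 360 / n_fold
  with_seed(seed, {
    stab <- numeric(reps); chng <- numeric(reps)
    for (i in seq_len(reps)) {
      th1 <- stats::runif(n_voxels, 0, period) * n_fold * pi / 180
      th2 <- stats::runif(n_voxels, 0, period) * n_fold * pi / 180
      m1 <- estimate_orientations(sin(th1), cos(th1), n_fold)
      m2 <- estimate_orientations(sin(th2), cos(th2), n_fold)
      stab[i] <- temporal_stability(m1, m2)
      chng[i] <- orientation_change(m1, m2)
    }
    list(mean_stability = mean(stab), mean_change = mean(chng),
         stability = stab, change = chng)
  })
}

#' Fold specificity of the cross-validated magnitude
#'
#' Simulates sessions with planted 6-fold modulation and evaluates the
#' cross-validated magnitude under the 5-, 6- and 7-fold models: only
#' the matching periodicity should yield positive magnitudes; the
#' control models should scatter around zero.
#'
#' @param n_seeds number of simulated sessions.
#' @param seed master seed.
#' @param n_runs,run_duration session shape.
#' @param n_voxels,amplitude,noise_sd planted-signal parameters.
#' @param planted_fold the symmetry actually planted.
#' @param folds models to evaluate.
#' @return matrix (n_seeds x folds) of magnitudes.
#' @export
fold_specificity_experiment <- function(n_seeds = 50, seed = 1,
                                        n_runs = 4, run_duration = 960,
                                        n_voxels = 12, amplitude = 0.5,
                                        noise_sd = 1, planted_fold = 6,
                                        folds = c(5, 6, 7)) {
  seeds <- derive_seeds(seed, 3 * n_seeds)
  out <- matrix(NA_real_, n_seeds, length(folds),
                dimnames = list(NULL, paste0("fold", folds)))
  for (i in seq_len(n_seeds)) {
    ev <- simulate_navigation_session(n_runs = n_runs,
                                      run_duration = run_duration,
                                      seed = seeds[3 * i - 2])
    pg <- planted_grid(n_voxels = n_voxels, spatial_sd = 0,
                       amplitude = amplitude, noise_sd = noise_sd,
                       n_fold = planted_fold, seed = seeds[3 * i - 1])
    bold <- generate_bold(ev, pg, seed = seeds[3 * i])
    cache <- new.env(parent = emptyenv())
    out[i, ] <- vapply(folds, function(nf)
      crossval_grid_magnitude(bold, ev, n_fold = nf,
                              cache = cache)$magnitude, 0)
  }
  out
}

#' End-to-end cohort pattern experiment
#'
#' Replicates the whole synthetic study end to end: generate a cohort,
#' run the grid and path-integration pipelines, and record whether the
#' qualitative result pattern holds — older group magnitude below the
#' young group's, negative old-group correlation between magnitude and
#' body-based path-integration error, and no systematic young-group
#' correlation.
#'
#' @param n_reps number of cohort replicates.
#' @param seed master seed.
#' @param spec_args arguments forwarded to [cohort_spec()] (the seed is
#'   set per replicate).
#' @return data.frame with one row per replicate: group magnitude
#'   means, old/young magnitude-error correlations, and the logical
#'   `pattern` flag.
#' @export
cohort_pattern_experiment <- function(n_reps = 100, seed = 1,
                                      spec_args = list()) {
  seeds <- derive_seeds(seed, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    spec <- do.call(cohort_spec, c(spec_args, list(seed = seeds[i])))
    tab <- cohort_table(spec, stability = FALSE)
    old <- tab[tab$group == "old", ]
    young <- tab[tab$group == "young", ]
    r_old <- stats::cor(old$magnitude, old$pi_error_body)
    ct_y <- stats::cor.test(young$magnitude, young$pi_error_body)
    rows[[i]] <- data.frame(
      rep = i, mag_old = mean(old$magnitude),
      mag_young = mean(young$magnitude),
      r_old = r_old, r_young = unname(ct_y$estimate),
      p_young = ct_y$p.value,
      pattern = mean(old$magnitude) < mean(young$magnitude) &&
        r_old < 0 && ct_y$p.value > 0.05)
  }
  do.call(rbind, rows)
}
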