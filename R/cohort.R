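#' Generate one synthetic participant
#'
#' Draws a participant's planted grid parameters and agent profile from
#' the group distributions of a [cohort_spec()], simulates the
#' navigation session, the grid-modulated BOLD data, and the
#' path-integration responses in both modalities, and assembles
#' covariates. In the old group (when coupling is on) the agent's
#' heading concentration and distance noise are tied log-linearly to
#' the planted grid amplitude, so that planted grid signal and planted
#' path-integration noise are negatively associated; young agents'
#' noise is drawn independently of their grid signal.
#'
#' @param spec a [cohort_spec()].
#' @param group `"young"` or `"old"`.
#' @param id participant id.
#' @param seed participant-level seed.
#' @param paths path set for the PI task.
#' @param session shared session design.
#' @param with_imaging simulate the navigation session and BOLD data?
#'   `FALSE` gives a behavioral-only participant (fast; used by
#'   generator-level Monte-Carlo checks).
#' @return list with `id`, `group`, `events`, `bold`, `pi_records`,
#'   `covariates` (one-row data.frame) and `truth` (planted parameters).
#' @export
generate_participant <- function(spec, group, id, seed,
                                 paths = default_path_set(),
                                 session = build_session(paths),
                                 with_imaging = TRUE) {
  g <- spec[[group]]
  seeds <- derive_seeds(seed, 8)
  with_seed(seeds[1], {
    amp <- max(g$amplitude_min,
               stats::rnorm(1, g$amplitude_mean, g$amplitude_sd))
    z <- (amp - g$amplitude_mean) / g$amplitude_sd
    couple <- spec$coupling && group == "old"
    kappa <- g$kappa * exp((if (couple) spec$coupling_strength * z else 0) +
                             stats::rnorm(1, 0, 0.25))
    cv <- g$cv * exp((if (couple) -0.5 * spec$coupling_strength * z else 0) +
                       stats::rnorm(1, 0, 0.15))
    agent <- agent_profile(
      distance_gain = exp(stats::rnorm(1, 0, 0.08)),
      distance_noise_cv = cv,
      heading_kappa = max(kappa, 0.5),
      verbal_scale = exp(stats::rnorm(1, 0, 0.2)))
    age <- round(min(max(stats::rnorm(1, mean(g$age_range),
                                      diff(g$age_range) / 4),
                         g$age_range[1]), g$age_range[2]), 1)
    covariates <- data.frame(
      id = id, group = group, age = age,
      sex = sample(c("female", "male"), 1),
      sbsod = round(min(max(stats::rnorm(1, 4.5, 0.9), 1), 7), 2),
      corsi = round(min(max(stats::rnorm(1, 5.5, 1), 2), 9)),
      tap_visual_scanning = round(stats::rnorm(1, 3200, 450)),
      tap_working_memory = round(stats::rnorm(1, 600, 90)),
      dsst = round(min(max(stats::rnorm(1, 45, 9), 10), 90)),
      moca = round(min(max(stats::rnorm(1, 26.5, 1.7), 24), 30)),
      ec_volume = round(stats::rnorm(1, 1500, 180)))
  })
  planted <- planted_grid(n_voxels = spec$n_voxels, spatial_sd = 5,
                          amplitude = amp, p_drift = g$p_drift,
                          drift_sd = g$drift_sd, noise_sd = g$noise_sd,
                          seed = seeds[2])
  if (with_imaging) {
    events <- simulate_navigation_session(arena_config(), spec$n_runs,
                                          spec$run_duration, seed = seeds[3])
    bold <- generate_bold(events, planted, tr = spec$tr, seed = seeds[4])
    covariates$mean_error_distance <-
      mean(attr(events, "trials")$error_distance)
  } else {
    events <- NULL; bold <- NULL
    covariates$mean_error_distance <- NA_real_
  }
  pi_records <- rbind(
    simulate_pi_responses(paths, agent, "body_based", seed = seeds[5],
                          session = session),
    simulate_pi_responses(paths, agent, "visual", seed = seeds[6],
                          session = session))
  list(id = id, group = group, events = events, bold = bold,
       pi_records = pi_records, covariates = covariates,
       truth = list(amplitude = amp, phi = planted$phi,
                    p_drift = g$p_drift, agent = agent, planted = planted))
}

#' Generate a full synthetic cohort
#'
#' 20 young and 21 older synthetic participants (by default), each with
#' a navigation session, BOLD data and path-integration responses, plus
#' ground truth for recovery tests. All participants share one session
#' design (fixed traversal order), as in the original study design.
#'
#' @param spec a [cohort_spec()].
#' @return list with `participants` (list of [generate_participant()]
#'   bundles), `covariates` (cohort table), `truth` (per-participant
#'   planted parameters), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  paths <- default_path_set()
  session <- build_session(paths)
  n <- spec$n_young + spec$n_old
  seeds <- derive_seeds(spec$seed, n)
  groups <- c(rep("young", spec$n_young), rep("old", spec$n_old))
  participants <- lapply(seq_len(n), function(i)
    generate_participant(spec, groups[i], i, seeds[i], paths, session))
  covariates <- do.call(rbind, lapply(participants, `[[`, "covariates"))
  # one older adult did not complete neuropsychological testing
  npsych <- c("sbsod", "corsi", "tap_visual_scanning",
              "tap_working_memory", "dsst", "moca")
  old_ids <- which(groups == "old")
  covariates[old_ids[length(old_ids)], npsych] <- NA
  truth <- data.frame(
    id = seq_len(n), group = groups,
    amplitude = vapply(participants, function(p) p$truth$amplitude, 0),
    phi = vapply(participants, function(p) p$truth$phi, 0),
    p_drift = vapply(participants, function(p) p$truth$p_drift, 0),
    heading_kappa = vapply(participants,
                           function(p) p$truth$agent$heading_kappa, 0),
    distance_noise_cv = vapply(participants,
                               function(p) p$truth$agent$distance_noise_cv, 0))
  list(participants = participants, covariates = covariates,
       truth = truth, spec = spec, paths = paths, session = session)
}

#' Analyze one participant bundle
#'
#' Runs the full per-participant analysis: cross-validated grid
#' magnitude for each requested fold, stability metrics, signal-quality
#' metrics, and path-integration scoring.
#'
#' @param p a [generate_participant()] bundle.
#' @param paths path set used for PI scoring.
#' @param folds directional symmetries to evaluate (6 plus controls).
#' @param stability compute the (costlier) per-half stability metrics?
#' @return one-row data.frame of participant-level measures.
#' @export
analyze_participant <- function(p, paths, folds = 6, stability = TRUE) {
  out <- p$covariates
  cache <- new.env(parent = emptyenv())
  for (nf in folds) {
    gr <- crossval_grid_magnitude(p$bold, p$events, n_fold = nf,
                                  cache = cache)
    out[[paste0("magnitude_", nf, "fold")]] <- gr$magnitude
    if (nf == 6) out$phi_hat <- gr$phi
  }
  out$magnitude <- out$magnitude_6fold
  if (stability) {
    st <- stability_summary(p$bold, p$events, cache = cache)
    out$temporal_stability <- st$temporal_stability
    out$mean_orientation_change <- st$mean_orientation_change
    out$rayleigh_z <- st$rayleigh_z
  }
  qm <- quality_metrics(p$bold)
  out$tsnr <- qm$tsnr
  out$mean_linear_disp <- qm$mean_linear_disp
  out$mean_angular_disp <- qm$mean_angular_disp
  pis <- score_pi_records(p$pi_records, paths)
  out$pi_error_body <- pis$body_based$mean_error
  out$pi_error_visual <- pis$visual$mean_error
  out$pi_perf_body <- pis$body_based$performance
  out$pi_perf_visual <- pis$visual$performance
  out
}

#' Simulate and analyze a cohort, streaming participants
#'
#' Runs [generate_participant()] and [analyze_participant()] one
#' participant at a time (BOLD data are dropped after analysis), and
#' returns the participant-level cohort table joined with the planted
#' ground truth. This is the entry point the acceptance experiments and
#' the pipeline use.
#'
#' @param spec a [cohort_spec()].
#' @param folds directional symmetries to evaluate.
#' @param stability compute stability metrics?
#' @return a `cohort_table` data.frame (one row per participant) with
#'   measures, covariates and `true_*` ground-truth columns.
#' @export
cohort_table <- function(spec = cohort_spec(), folds = 6,
                         stability = TRUE) {
  paths <- default_path_set()
  session <- build_session(paths)
  n <- spec$n_young + spec$n_old
  seeds <- derive_seeds(spec$seed, n)
  groups <- c(rep("young", spec$n_young), rep("old", spec$n_old))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_participant(spec, groups[i], i, seeds[i], paths, session)
    row <- analyze_participant(p, paths, folds = folds,
                               stability = stability)
    row$true_amplitude <- p$truth$amplitude
    row$true_phi <- p$truth$phi
    row$true_kappa <- p$truth$agent$heading_kappa
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  npsych <- c("sbsod", "corsi", "tap_visual_scanning",
              "tap_working_memory", "dsst", "moca")
  old_ids <- which(out$group == "old")
  out[old_ids[length(old_ids)], npsych] <- NA
  class(out) <- c("cohort_table", "data.frame")
  out
}
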