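#' Arena configuration for the object-location memory task
#'
#' Parameters of the square virtual room used in the navigation task:
#' a 160 x 160 virtual-meter (vm) arena, constant translation speed of
#' 15 vm/s, constant rotation speed of 50 deg/s, three target objects,
#' and feedback thresholds at 20 vm (green) and 30 vm (yellow) error
#' distance.
#'
#' @param side_length arena side length in vm.
#' @param move_speed translation speed in vm/s.
#' @param rotation_speed rotation speed in deg/s.
#' @param n_objects number of target objects.
#' @param feedback_thresholds numeric length-2, (green, yellow) error
#'   distance thresholds in vm, strictly increasing and positive.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(side_length = 160, move_speed = 15,
                         rotation_speed = 50, n_objects = 3,
                         feedback_thresholds = c(20, 30)) {
  if (!is.numeric(side_length) || side_length <= 0)
    stop("side_length must be > 0")
  if (!is.numeric(move_speed) || move_speed <= 0)
    stop("move_speed must be > 0")
  if (!is.numeric(rotation_speed) || rotation_speed <= 0)
    stop("rotation_speed must be > 0")
  if (n_objects < 1) stop("n_objects must be >= 1")
  ft <- feedback_thresholds
  if (length(ft) != 2 || ft[1] <= 0 || ft[2] <= ft[1])
    stop("feedback_thresholds must satisfy 0 < green < yellow")
  structure(list(side_length = side_length, move_speed = move_speed,
                 rotation_speed = rotation_speed, n_objects = n_objects,
                 feedback_thresholds = ft),
            class = "arena_config")
}

#' Planted grid ground truth for the BOLD forward model
#'
#' Defines, per voxel, the true grid orientation on the 60-degree domain
#' (for `n_fold = 6`), the amplitude of the hexadirectional modulation,
#' the temporal-drift model (probability of an orientation redraw at each
#' half-run boundary, plus Gaussian jitter), and the noise level.
#' Voxel orientations are drawn around a shared participant-level
#' orientation with wrapped-Gaussian spatial jitter, mimicking the
#' spatial coherence of voxel orientations within an ROI.
#'
#' @param n_voxels number of voxels in the ROI.
#' @param phi participant-level grid orientation in degrees on
#'   `[0, 360/n_fold)`; `NULL` draws it uniformly (requires `seed`).
#' @param spatial_sd wrapped-Gaussian SD (deg) of voxel orientations
#'   around `phi`; 0 means perfectly coherent voxels.
#' @param phi_v optional explicit per-voxel orientations (degrees on
#'   `[0, 360/n_fold)`), overriding `phi`/`spatial_sd`.
#' @param amplitude hexadirectional modulation amplitude, signal units
#'   (scalar or per voxel).
#' @param main_amplitude amplitude of the unmodulated translation main
#'   effect, signal units.
#' @param p_drift probability that a voxel's orientation is redrawn
#'   uniformly at each half-run boundary.
#' @param drift_sd SD (deg) of Gaussian orientation jitter applied at
#'   each half-run boundary.
#' @param noise_sd Gaussian scan noise SD, signal units.
#' @param baseline signal baseline.
#' @param ar1 AR(1) coefficient for temporally correlated noise
#'   (0 = white noise).
#' @param n_fold directional symmetry of the planted modulation.
#' @param seed RNG seed used when drawing `phi` and voxel jitter.
#' @return an object of class `planted_grid` with element `phi_v`
#'   (per-voxel orientations in degrees).
#' @export
planted_grid <- function(n_voxels = 30, phi = NULL, spatial_sd = 5,
                         amplitude = 1, main_amplitude = 1,
                         p_drift = 0, drift_sd = 0, noise_sd = 1,
                         baseline = 100, ar1 = 0, n_fold = 6,
                         seed = NULL, phi_v = NULL) {
  period <- 360 / n_fold
  if (!is.null(phi_v)) {
    if (length(phi_v) != n_voxels || any(phi_v < 0 | phi_v >= period))
      stop(sprintf("phi_v must have %d entries in [0, %g)", n_voxels, period))
    phi <- wrap_deg(atan2(mean(sin(n_fold * phi_v * pi / 180)),
                          mean(cos(n_fold * phi_v * pi / 180))) *
                      180 / pi / n_fold, period)
  } else if (is.null(phi)) {
    if (is.null(seed)) stop("supply phi or a seed to draw it")
    phi <- with_seed(seed, stats::runif(1, 0, period))
  }
  if (any(phi < 0 | phi >= period))
    stop(sprintf("phi must lie in [0, %g)", period))
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (p_drift < 0 || p_drift > 1) stop("p_drift must be in [0, 1]")
  if (drift_sd < 0) stop("drift_sd must be >= 0")
  if (is.null(phi_v)) phi_v <- if (spatial_sd > 0) {
    if (is.null(seed)) stop("supply a seed to draw voxel orientations")
    with_seed(seed + 1L,
              wrap_deg(phi + stats::rnorm(n_voxels, 0, spatial_sd), period))
  } else rep(phi, n_voxels)
  phi_v <- rep_len(phi_v, n_voxels)
  structure(list(n_voxels = n_voxels, phi = phi, phi_v = phi_v,
                 amplitude = rep_len(amplitude, n_voxels),
                 main_amplitude = main_amplitude,
                 p_drift = p_drift, drift_sd = drift_sd,
                 noise_sd = noise_sd, baseline = baseline, ar1 = ar1,
                 n_fold = n_fold),
            class = "planted_grid")
}

#' Path-integration agent noise profile
#'
#' A generative stand-in for a participant's response process in the
#' multi-stop path-integration task: responded distances are the true
#' distances times a multiplicative path-integration gain, times a
#' verbal scale (what the agent "calls a meter"), times mean-one
#' lognormal noise with the given coefficient of variation; responded
#' bearings are the true bearings plus von Mises noise.
#' Standardization (straight calibration) paths are scaled by the same
#' verbal scale but not by the path-integration gain, so the
#' standardization correction can remove exactly the verbal component.
#'
#' @param distance_gain multiplicative path-integration distance bias (> 0).
#' @param distance_noise_cv coefficient of variation of distance noise (>= 0).
#' @param heading_kappa von Mises concentration of bearing noise
#'   (> 0; `Inf` = noiseless headings).
#' @param verbal_scale multiplicative verbal meter bias (> 0).
#' @return an object of class `agent_profile`.
#' @export
agent_profile <- function(distance_gain = 1, distance_noise_cv = 0,
                          heading_kappa = Inf, verbal_scale = 1) {
  if (distance_gain <= 0) stop("distance_gain must be > 0")
  if (distance_noise_cv < 0) stop("distance_noise_cv must be >= 0")
  if (!(heading_kappa > 0)) stop("heading_kappa must be > 0")
  if (verbal_scale <= 0) stop("verbal_scale must be > 0")
  structure(list(distance_gain = distance_gain,
                 distance_noise_cv = distance_noise_cv,
                 heading_kappa = heading_kappa,
                 verbal_scale = verbal_scale),
            class = "agent_profile")
}

#' Cohort specification for the synthetic study
#'
#' Defines the two-group study structure: 20 young and 21 older
#' participants, each with a navigation session, grid-modulated BOLD
#' data, and path-integration responses. The "old" group is drawn with
#' lower grid amplitude and unstable orientations (half-run drift), and
#' its agent noise is coupled to grid amplitude (lower amplitude =>
#' noisier path integration), planting a negative magnitude-error
#' association; young agents' noise is independent of their grid signal.
#'
#' @param n_young,n_old group sizes.
#' @param n_runs,run_duration scanning session shape (default four
#'   16-minute runs).
#' @param tr repetition time in seconds.
#' @param n_voxels ROI voxel count per participant.
#' @param young,old per-group parameter lists; see Details.
#' @param coupling logical: couple old-group agent noise to grid
#'   amplitude?
#' @param coupling_strength log-linear slope of agent noise on planted
#'   amplitude in the old group.
#' @param seed integer seed for the whole cohort.
#'
#' @details `young` and `old` are lists with elements
#'   `amplitude_mean`, `amplitude_sd` (truncated at `amplitude_min`),
#'   `p_drift`, `drift_sd`, `noise_sd`, `kappa` (median heading
#'   concentration), `cv` (median distance noise CV), `age_range`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 20, n_old = 21,
                        n_runs = 4, run_duration = 960, tr = 1.5,
                        n_voxels = 30,
                        young = list(amplitude_mean = 1.0, amplitude_sd = 0.3,
                                     amplitude_min = 0.2, p_drift = 0.05,
                                     drift_sd = 2, noise_sd = 1,
                                     kappa = 35, cv = 0.12,
                                     age_range = c(19, 30)),
                        old = list(amplitude_mean = 0.45, amplitude_sd = 0.3,
                                   amplitude_min = 0.05, p_drift = 0.5,
                                   drift_sd = 3, noise_sd = 1,
                                   kappa = 12, cv = 0.25,
                                   age_range = c(63, 81)),
                        coupling = TRUE, coupling_strength = 1.5,
                        seed = 1L) {
  if (n_young < 1 || n_old < 1) stop("group sizes must be positive")
  structure(list(n_young = n_young, n_old = n_old, n_runs = n_runs,
                 run_duration = run_duration, tr = tr, n_voxels = n_voxels,
                 young = young, old = old, coupling = coupling,
                 coupling_strength = coupling_strength, seed = seed),
            class = "cohort_spec")
}
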