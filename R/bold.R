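#' Generate grid-modulated BOLD-like voxel time series
#'
#' Forward model of the hexadirectional effect the split-half GLM
#' analysis is designed to detect. Per voxel v with orientation
#' `phi_v`, every translation event with direction `alpha` contributes a
#' boxcar of height `amplitude * cos(n_fold * (alpha - phi_v))` plus an
#' unmodulated translation main effect; boxcars are convolved with the
#' canonical HRF, sampled at the scan times, and baseline, Gaussian
#' (optionally AR(1)) noise and simulated head-motion parameters are
#' added. If `p_drift > 0` (or `drift_sd > 0`), voxel orientations are
#' redrawn/perturbed at each half-run boundary — the generative
#' mechanism for temporally unstable, "old-age-like" grid
#' representations. The orientations actually in force in each half-run
#' are returned as ground truth.
#'
#' @param events an `event_table` (must contain translation events).
#' @param planted a [planted_grid()].
#' @param tr repetition time in seconds.
#' @param seed RNG seed for noise, drift and motion.
#' @param phi_segments optional matrix (n_voxels x 2*n_runs) of
#'   per-half-run orientations overriding the drift simulation — used by
#'   designed experiments that impose an exact orientation change
#'   between data halves.
#' @param motion_sd per-scan SD of the random-walk motion parameters
#'   (mm / deg).
#' @param motion_artifact amplitude of a motion-correlated signal
#'   artifact added to every voxel (0 = none).
#' @return an object of class `voxel_ts`: list with `runs` (each with
#'   `signal` = voxels x scans matrix and `motion` = scans x 6 matrix),
#'   `tr`, `voxel_ids`, and attribute `ground_truth` holding the
#'   per-half-run orientation log.
#' @export
generate_bold <- function(events, planted, tr = 1.5, seed = 1,
                          phi_segments = NULL, motion_sd = 0.02,
                          motion_artifact = 0) {
  stopifnot(inherits(planted, "planted_grid"))
  if (tr <= 0) stop("TR must be > 0")
  tra <- events[events$kind == "translation", ]
  if (nrow(tra) == 0) stop("no translation events: nothing to modulate")
  run_dur <- attr(events, "run_durations")
  runs <- sort(unique(events$run_id))
  n_runs <- length(runs)
  nv <- planted$n_voxels
  nf <- planted$n_fold
  period <- 360 / nf

  with_seed(seed, {
    # per-half-run orientation trajectory (segments ordered run1-half1,
    # run1-half2, run2-half1, ...)
    n_seg <- 2L * n_runs
    if (is.null(phi_segments)) {
      phi_segments <- matrix(0, nv, n_seg)
      phi_segments[, 1] <- planted$phi_v
      for (s in seq_len(n_seg)[-1]) {
        redraw <- stats::runif(nv) < planted$p_drift
        base <- ifelse(redraw, stats::runif(nv, 0, period),
                       phi_segments[, s - 1L])
        jit <- if (planted$drift_sd > 0)
          stats::rnorm(nv, 0, planted$drift_sd) else 0
        phi_segments[, s] <- wrap_deg(base + jit, period)
      }
    } else {
      stopifnot(nrow(phi_segments) == nv, ncol(phi_segments) == n_seg)
    }

    run_list <- vector("list", n_runs)
    for (ri in seq_along(runs)) {
      r <- runs[ri]
      dur <- run_dur[[as.character(r)]]
      n_scans <- floor(dur / tr)
      mid <- n_scans * tr / 2
      e <- tra[tra$run_id == r, ]
      half <- ifelse(e$onset < mid, 1L, 2L)
      sig <- matrix(planted$baseline, nv, n_scans)
      main <- convolve_events(e$onset, e$duration,
                              rep(1, nrow(e)), n_scans, tr)
      sig <- sig + planted$main_amplitude *
        matrix(main, nv, n_scans, byrow = TRUE)
      for (h in 1:2) {
        eh <- e[half == h, ]
        if (nrow(eh) == 0) next
        a <- eh$direction * pi / 180
        cc <- convolve_events(eh$onset, eh$duration, cos(nf * a), n_scans, tr)
        ss <- convolve_events(eh$onset, eh$duration, sin(nf * a), n_scans, tr)
        ph <- phi_segments[, 2L * (ri - 1L) + h] * pi / 180
        w_c <- planted$amplitude * cos(nf * ph)
        w_s <- planted$amplitude * sin(nf * ph)
        sig <- sig + outer(w_c, cc) + outer(w_s, ss)
      }
      motion <- apply(matrix(stats::rnorm(n_scans * 6, 0, motion_sd),
                             n_scans, 6), 2, cumsum)
      colnames(motion) <- c("x", "y", "z", "yaw", "pitch", "roll")
      if (motion_artifact != 0)
        sig <- sig + motion_artifact *
          matrix(rowSums(motion), nv, n_scans, byrow = TRUE)
      if (planted$noise_sd > 0) {
        eps <- matrix(stats::rnorm(nv * n_scans, 0, planted$noise_sd),
                      nv, n_scans)
        if (planted$ar1 != 0) {
          eps <- t(apply(eps, 1, function(x)
            stats::filter(x, planted$ar1, method = "recursive"))) *
            sqrt(1 - planted$ar1^2)
        }
        sig <- sig + eps
      }
      run_list[[ri]] <- list(signal = sig, motion = motion,
                             n_scans = n_scans, run_id = r)
    }
    structure(list(runs = run_list, tr = tr,
                   voxel_ids = seq_len(nv)),
              class = "voxel_ts",
              ground_truth = list(phi_segments = phi_segments,
                                  planted = planted))
  })
}
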