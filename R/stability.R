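#' Temporal stability of voxel-wise grid orientations
#'
#' A voxel is "stable" if its orientation in the two data halves differs
#' by at most 15 degrees (inclusive) on the 60-degree-periodic domain
#' (more generally, by at most a quarter period of the n-fold model).
#' Under independent uniform orientations the expected proportion of
#' stable voxels is exactly 0.5, the chance level.
#'
#' @param map_first,map_second `orientation_map`s over the same voxels.
#' @param threshold stability threshold in degrees (default a quarter
#'   period, 15 for n = 6).
#' @return proportion of stable voxels in `[0, 1]`.
#' @export
temporal_stability <- function(map_first, map_second, threshold = NULL) {
  check_same_voxels(map_first, map_second)
  period <- 360 / attr(map_first, "n_fold")
  if (is.null(threshold)) threshold <- period / 4
  d <- circ_diff_deg(map_first$orientation, map_second$orientation, period)
  # inclusive boundary, robust to wrap-around round-off
  mean(d <= threshold + 1e-9)
}

#' Mean absolute orientation change between data halves
#'
#' The per-voxel absolute circular change in grid orientation (period
#' 60 degrees for n = 6, so the maximum is 30), averaged over voxels.
#' Under independent uniform orientations the expectation is a quarter
#' period (15 degrees).
#'
#' @inheritParams temporal_stability
#' @return mean absolute circular orientation change in degrees.
#' @export
orientation_change <- function(map_first, map_second) {
  check_same_voxels(map_first, map_second)
  period <- 360 / attr(map_first, "n_fold")
  mean(circ_diff_deg(map_first$orientation, map_second$orientation, period))
}

#' Spatial stability (orientation coherence) of an orientation map
#'
#' Coherence of voxel-wise grid orientations across the ROI, scored by
#' Rayleigh's test for non-uniformity after mapping the
#' `360/n`-degree-periodic orientations onto the full circle
#' (multiplication by n; required for a circular test on periodic
#' orientations). Higher z means higher spatial stability.
#'
#' @param map an `orientation_map` with at least 2 voxels.
#' @return list with `rayleigh_z` and `rayleigh_p`.
#' @export
spatial_stability <- function(map) {
  if (nrow(map) < 2) stop("need at least 2 voxels")
  n_fold <- attr(map, "n_fold")
  rt <- rayleigh_test(wrap_deg(map$orientation * n_fold))
  list(rayleigh_z = rt$z, rayleigh_p = rt$p)
}

check_same_voxels <- function(a, b) {
  if (!identical(a$voxel, b$voxel))
    stop("orientation maps cover different voxel sets")
  if (!identical(attr(a, "n_fold"), attr(b, "n_fold")))
    stop("orientation maps have different n_fold")
  invisible(TRUE)
}

#' Session-level stability summary
#'
#' Computes the paper-style stability indicators for one session:
#' voxel orientations are estimated separately for each half of every
#' scanning run; temporal stability (proportion of voxels within +/-15
#' degrees between halves) and mean absolute orientation change are
#' averaged across runs; spatial stability is the Rayleigh z of each
#' run's estimation-half orientations, averaged across runs (pooled
#' variant available).
#'
#' @inheritParams crossval_grid_magnitude
#' @param spatial one of `"per_run"` (average of per-run z values,
#'   default) or `"pooled"` (one test on all runs' estimation-half
#'   orientations pooled).
#' @param cache optional convolution cache environment.
#' @return a `stability_result`: list with `temporal_stability`,
#'   `mean_orientation_change`, `rayleigh_z`, `rayleigh_p`, `n_voxels`,
#'   `per_run` (per-run temporal stability).
#' @export
stability_summary <- function(ts, events, n_fold = 6, min_duration = 1,
                              spatial = c("per_run", "pooled"),
                              cache = NULL) {
  spatial <- match.arg(spatial)
  maps <- orientation_maps_by_half(ts, events, n_fold, min_duration, cache)
  if (!length(maps)) stop("no runs with estimable orientations")
  ts_run <- vapply(maps, function(m) temporal_stability(m$first, m$second), 0)
  ch_run <- vapply(maps, function(m) orientation_change(m$first, m$second), 0)
  if (spatial == "per_run") {
    zs <- vapply(maps, function(m) spatial_stability(m$first)$rayleigh_z, 0)
    ps <- vapply(maps, function(m) spatial_stability(m$first)$rayleigh_p, 0)
    z <- mean(zs); p <- mean(ps)
  } else {
    ori <- unlist(lapply(maps, function(m) m$first$orientation))
    rt <- rayleigh_test(wrap_deg(ori * n_fold))
    z <- rt$z; p <- rt$p
  }
  structure(list(temporal_stability = mean(ts_run),
                 mean_orientation_change = mean(ch_run),
                 rayleigh_z = z, rayleigh_p = p,
                 n_voxels = nrow(maps[[1]]$first),
                 per_run = ts_run),
            class = "stability_result")
}
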