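#' Split runs into estimation and test halves
#'
#' Partitions each scanning run at its temporal midpoint: the first half
#' of every run is the estimation dataset (used to estimate grid
#' orientations), the second half the test dataset (used to quantify
#' the cross-validated magnitude). An event belongs to the half that
#' contains its onset; an onset exactly at the midpoint goes to the
#' second half.
#'
#' @param events an `event_table`.
#' @param ts a `voxel_ts` (defines the scan grid); may be `NULL` when
#'   only the event partition is needed.
#' @param tr repetition time in seconds (taken from `ts` when given).
#' @return list with `estimation` and `test`, each a list of
#'   `events` (event_table subset), and per-run scan index lists
#'   `scan_idx`; plus `excluded_runs`, runs lacking translation events
#'   in one of the halves (flagged with a warning).
#' @export
split_halves <- function(events, ts = NULL, tr = if (!is.null(ts)) ts$tr else 1.5) {
  run_dur <- attr(events, "run_durations")
  runs <- sort(unique(events$run_id))
  half_of <- integer(nrow(events))
  scan_idx <- list(estimation = list(), test = list())
  excluded <- integer(0)
  for (r in runs) {
    dur <- run_dur[[as.character(r)]]
    n_scans <- floor(dur / tr)
    if (!is.null(ts)) {
      ri <- which(vapply(ts$runs, function(x) x$run_id, 0) == r)
      n_scans <- min(n_scans, ts$runs[[ri]]$n_scans)
    }
    mid <- n_scans * tr / 2
    sel <- events$run_id == r
    half_of[sel] <- ifelse(events$onset[sel] < mid, 1L, 2L)
    scan_times <- (seq_len(n_scans) - 1L) * tr
    scan_idx$estimation[[as.character(r)]] <- which(scan_times < mid)
    scan_idx$test[[as.character(r)]] <- which(scan_times >= mid)
    tr_sel <- sel & events$kind == "translation"
    if (!any(half_of[tr_sel] == 1L) || !any(half_of[tr_sel] == 2L))
      excluded <- c(excluded, r)
  }
  if (length(excluded))
    warning("runs without translation events in one half, excluded from ",
            "orientation averaging: ", paste(excluded, collapse = ", "))
  subset_ev <- function(h) {
    out <- events[half_of == h, , drop = FALSE]
    attr(out, "run_durations") <- run_dur
    class(out) <- class(events)
    out
  }
  list(estimation = list(events = subset_ev(1L),
                         scan_idx = scan_idx$estimation),
       test = list(events = subset_ev(2L), scan_idx = scan_idx$test),
       excluded_runs = excluded)
}

# Per-run scan counts used for design assembly (respects reduced
# run durations: uses the smaller of the time series and the event
# table's run duration).
run_scan_counts <- function(events, ts, tr) {
  run_dur <- attr(events, "run_durations")
  runs <- sort(unique(events$run_id))
  vapply(runs, function(r) {
    n <- floor(run_dur[[as.character(r)]] / tr)
    if (!is.null(ts)) {
      ri <- which(vapply(ts$runs, function(x) x$run_id, 0) == r)
      n <- min(n, ts$runs[[ri]]$n_scans)
    }
    as.integer(n)
  }, 0L)
}

#' Build the GLM design matrix for grid-orientation analysis
#'
#' Assembles, over all runs, the design of the estimation model (GLM1:
#' translation main effect plus quadrature parametric modulators
#' `sin(n alpha)` and `cos(n alpha)`) or the test model (GLM2: main
#' effect plus one aligned modulator `cos(n (alpha - phi))` built from a
#' supplied orientation estimate). Parametric weights are mean-centered
#' across the modeled translation events before boxcar construction.
#' Nuisance columns: the unused half's translation events as an
#' unmodulated boxcar, the feedback phase, the six head-motion
#' parameters, and one intercept per run. Translation events shorter
#' than `min_duration` seconds (strictly) are not modeled.
#'
#' @param events full `event_table` for the session.
#' @param ts `voxel_ts` supplying TR, scan counts and motion parameters.
#' @param n_fold directional symmetry (5, 6 or 7 in the standard set).
#' @param phi mean grid orientation in degrees (required for
#'   `role = "test"`).
#' @param role `"estimation"` (GLM1) or `"test"` (GLM2).
#' @param min_duration shortest modeled translation duration (s).
#' @param cache optional environment memoizing convolved columns
#'   across designs of the same session.
#' @return list with `X` (scans x columns), `rows` (logical fit-scan
#'   selector covering the role's half), `interest` (names of the
#'   modulator columns), `run_of_row`, and `events_modeled`.
#' @export
build_design_matrix <- function(events, ts, n_fold = 6, phi = NULL,
                                role = c("estimation", "test"),
                                min_duration = 1, cache = NULL) {
  role <- match.arg(role)
  if (role == "test" && is.null(phi))
    stop("role = 'test' requires phi")
  grid_design(events, ts, n_fold,
              half = if (role == "estimation") 1L else 2L,
              type = if (role == "estimation") "quadrature" else "aligned",
              phi = phi, min_duration = min_duration, cache = cache)
}

# Core design assembly: quadrature (sin/cos) or aligned modulators for
# the events of one half (1 = first/estimation, 2 = second/test), with
# the other half's events as an unmodulated nuisance boxcar. An
# optional cache environment memoizes convolved columns shared between
# designs of the same session (the estimation half's main boxcar is the
# test design's unused-events nuisance and vice versa).
grid_design <- function(events, ts, n_fold, half, type, phi = NULL,
                        min_duration = 1, cache = NULL) {
  tr <- ts$tr
  halves <- split_halves(events, ts)
  own <- if (half == 1L) halves$estimation else halves$test
  other <- if (half == 1L) halves$test else halves$estimation
  keep <- own$events$kind == "translation" &
    own$events$duration >= min_duration
  modeled <- own$events[keep, , drop = FALSE]
  if (nrow(modeled) == 0) stop("no modelable events")
  unused <- other$events[other$events$kind == "translation" &
                           other$events$duration >= min_duration, ,
                         drop = FALSE]
  fb <- events[events$kind == "feedback", , drop = FALSE]

  a <- modeled$direction * pi / 180
  if (type == "quadrature") {
    wts <- list(sin = sin(n_fold * a), cos = cos(n_fold * a))
  } else {
    wts <- list(aligned = cos(n_fold * (a - phi * pi / 180)))
  }
  wts <- lapply(wts, function(w) w - mean(w))

  n_scans <- run_scan_counts(events, ts, tr)
  runs <- sort(unique(events$run_id))
  blocks <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[i]
    ns <- n_scans[i]
    conv_r <- function(e, h, key = NULL) {
      if (!is.null(cache) && !is.null(key)) {
        key <- sprintf("%s_r%s", key, r)
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
      }
      e <- e[e$run_id == r, , drop = FALSE]
      out <- convolve_events(e$onset, e$duration, rep_len(h, nrow(e)),
                             ns, tr)
      if (!is.null(cache) && !is.null(key)) cache[[key]] <- out
      out
    }
    cols <- list(main = conv_r(modeled, 1, sprintf("main_h%d", half)))
    for (nm in names(wts)) {
      key <- if (type == "quadrature")
        sprintf("%s%d_h%d", nm, n_fold, half)
      else sprintf("aligned%d_%.8f_h%d", n_fold, phi, half)
      cols[[nm]] <- conv_r(modeled, wts[[nm]][modeled$run_id == r], key)
    }
    cols$unused <- conv_r(unused, 1, sprintf("main_h%d", 3L - half))
    cols$feedback <- conv_r(fb, 1, "feedback")
    ri <- which(vapply(ts$runs, function(x) x$run_id, 0) == r)
    mot <- ts$runs[[ri]]$motion[seq_len(ns), , drop = FALSE]
    X <- cbind(do.call(cbind, cols), mot)
    colnames(X) <- c(names(cols), paste0("motion_", colnames(mot)))
    blocks[[i]] <- X
  }
  X <- do.call(rbind, blocks)
  run_of_row <- rep(runs, n_scans)
  for (r in runs) {
    ic <- as.numeric(run_of_row == r)
    X <- cbind(X, ic)
    colnames(X)[ncol(X)] <- paste0("intercept_run", r)
  }
  rows <- logical(nrow(X))
  offset <- c(0, cumsum(n_scans))
  for (i in seq_along(runs)) {
    idx <- own$scan_idx[[as.character(runs[i])]]
    rows[offset[i] + idx] <- TRUE
  }
  list(X = X, rows = rows, interest = names(wts),
       run_of_row = run_of_row, events_modeled = modeled,
       n_fold = n_fold, half = half, type = type, phi = phi)
}

#' Fit a mass-univariate ordinary least squares GLM
#'
#' Fits the same design to every voxel's time series by QR-based least
#' squares, restricted to the design's fit rows (the scans of the
#' estimation or test half).
#'
#' @param ts a `voxel_ts`.
#' @param design output of [build_design_matrix()], or a list with
#'   elements `X` and (optionally) `rows`.
#' @param run_subset optional run ids to restrict the fit to.
#' @return list with `betas` (voxels x columns), `sigma2` residual
#'   variances, `se` standard errors per coefficient, `df` residual
#'   degrees of freedom.
#' @export
fit_glm <- function(ts, design, run_subset = NULL) {
  Y <- do.call(cbind, lapply(ts$runs, function(r) r$signal))
  scans_per_run <- vapply(ts$runs, function(r) as.numeric(r$n_scans), 0)
  # design may cover fewer scans per run (reduced runs): align columns
  if (ncol(Y) != nrow(design$X)) {
    keep <- unlist(lapply(seq_along(ts$runs), function(i) {
      n_design <- sum(design$run_of_row == ts$runs[[i]]$run_id)
      off <- c(0, cumsum(scans_per_run))[i]
      off + seq_len(n_design)
    }))
    Y <- Y[, keep, drop = FALSE]
  }
  rows <- if (!is.null(design$rows)) design$rows else rep(TRUE, nrow(design$X))
  if (!is.null(run_subset))
    rows <- rows & design$run_of_row %in% run_subset
  X <- design$X[rows, , drop = FALSE]
  # drop all-zero columns (e.g. intercepts of runs outside the subset)
  nz <- colSums(abs(X)) > 0
  X <- X[, nz, drop = FALSE]
  Yf <- t(Y[, rows, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, Yf)
  res <- Yf - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))
  se <- sqrt(outer(sigma2, XtXinv_diag))
  colnames(se) <- colnames(X)
  betas <- t(B)
  colnames(betas) <- colnames(X)
  list(betas = betas, sigma2 = sigma2, se = se, df = df)
}

#' Estimate voxel-wise and mean grid orientations from quadrature betas
#'
#' Voxel orientation = `atan2(beta_sin, beta_cos) / n` mapped into
#' `[0, 360/n)`. The ROI mean orientation phi is computed from the
#' ROI-averaged betas — average first, then atan2 — never by averaging
#' voxel orientations.
#'
#' @param beta_sin,beta_cos per-voxel coefficients of the sine and
#'   cosine modulators.
#' @param n_fold directional symmetry (6 for the hexadirectional model).
#' @return an `orientation_map`: data.frame with `voxel`, `beta_sin`,
#'   `beta_cos`, `orientation`; attributes `phi` (ROI mean orientation,
#'   degrees) and `n_fold`.
#' @export
#' @examples
#' m <- estimate_orientations(beta_sin = c(1, 1), beta_cos = c(0, 0))
#' attr(m, "phi")  # 15: atan2(1,0) = 90 degrees, / 6
estimate_orientations <- function(beta_sin, beta_cos, n_fold = 6) {
  stopifnot(length(beta_sin) == length(beta_cos))
  if (any(!is.finite(beta_sin)) || any(!is.finite(beta_cos)))
    stop("betas must be finite")
  period <- 360 / n_fold
  ang <- atan2(beta_sin, beta_cos) * 180 / pi
  orientation <- wrap_deg(ang / n_fold, period)
  mb_s <- mean(beta_sin); mb_c <- mean(beta_cos)
  if (mb_s == 0 && mb_c == 0) stop("orientation undefined: mean betas are 0")
  phi <- wrap_deg(atan2(mb_s, mb_c) * 180 / pi / n_fold, period)
  structure(data.frame(voxel = seq_along(beta_sin), beta_sin = beta_sin,
                       beta_cos = beta_cos, orientation = orientation),
            phi = phi, n_fold = n_fold,
            class = c("orientation_map", "data.frame"))
}

#' Cross-validated grid-cell-like magnitude
#'
#' The full split-half procedure: estimate the mean grid orientation phi
#' from the estimation halves (GLM1, pooled over runs with per-run
#' intercepts), then fit the aligned modulator `cos(n (alpha - phi))` on
#' the test halves (GLM2) and report the ROI-mean aligned beta as the
#' magnitude of the grid-cell-like representation. The magnitude is
#' positive when the orientation change between halves is under 15
#' degrees (for n = 6) and negative beyond, reaching its minimum at the
#' maximal detectable change of 30 degrees.
#'
#' @param ts a `voxel_ts`.
#' @param events the session's `event_table`.
#' @param n_fold directional symmetry; 6 is the grid model, 5 and 7 the
#'   standard control periodicities.
#' @param min_duration shortest modeled translation duration (s).
#' @param per_run if `TRUE`, GLM2 is fit per run and magnitudes
#'   averaged; default is one joint fit with per-run intercepts.
#' @param cache optional convolution cache environment (see
#'   [build_design_matrix()]).
#' @return a `grid_result`: list with `magnitude`, `phi`, `n_fold`,
#'   `voxel_aligned_betas`, `orientation_map` (estimation halves),
#'   `per_run_magnitude` (when requested), `excluded_runs`, `settings`.
#' @export
crossval_grid_magnitude <- function(ts, events, n_fold = 6,
                                    min_duration = 1, per_run = FALSE,
                                    cache = NULL) {
  halves <- split_halves(events, ts)
  keep_runs <- setdiff(vapply(ts$runs, function(r) r$run_id, 0),
                       halves$excluded_runs)
  d1 <- build_design_matrix(events, ts, n_fold, role = "estimation",
                            min_duration = min_duration, cache = cache)
  f1 <- fit_glm(ts, d1, run_subset = keep_runs)
  omap <- estimate_orientations(f1$betas[, "sin"], f1$betas[, "cos"],
                                n_fold = n_fold)
  phi <- attr(omap, "phi")
  d2 <- build_design_matrix(events, ts, n_fold, phi = phi, role = "test",
                            min_duration = min_duration, cache = cache)
  if (per_run) {
    mags <- vapply(keep_runs, function(r) {
      f <- fit_glm(ts, d2, run_subset = r)
      mean(f$betas[, "aligned"])
    }, 0)
    magnitude <- mean(mags)
    per_run_magnitude <- stats::setNames(mags, keep_runs)
    va <- NULL
  } else {
    f2 <- fit_glm(ts, d2, run_subset = keep_runs)
    va <- f2$betas[, "aligned"]
    magnitude <- mean(va)
    per_run_magnitude <- NULL
  }
  structure(list(magnitude = magnitude, phi = phi, n_fold = n_fold,
                 voxel_aligned_betas = va, orientation_map = omap,
                 per_run_magnitude = per_run_magnitude,
                 excluded_runs = halves$excluded_runs,
                 settings = list(min_duration = min_duration,
                                 per_run = per_run)),
            class = "grid_result")
}

#' Per-half voxel orientation maps for stability analysis
#'
#' Estimates voxel-wise grid orientations separately for the first and
#' second half of each scanning run (each half gets its own GLM1 fit on
#' that run only), as required by the temporal-stability metric.
#'
#' @inheritParams crossval_grid_magnitude
#' @param cache optional convolution cache environment.
#' @return list (one element per run) of lists with `first` and
#'   `second` `orientation_map`s; runs lacking modelable events in a
#'   half are skipped with a warning.
#' @export
orientation_maps_by_half <- function(ts, events, n_fold = 6,
                                     min_duration = 1, cache = NULL) {
  runs <- vapply(ts$runs, function(r) r$run_id, 0)
  designs <- lapply(1:2, function(h)
    grid_design(events, ts, n_fold, half = h, type = "quadrature",
                min_duration = min_duration, cache = cache))
  out <- list()
  for (r in runs) {
    maps <- lapply(designs, function(d) {
      f <- tryCatch(fit_glm(ts, d, run_subset = r),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      estimate_orientations(f$betas[, "sin"], f$betas[, "cos"], n_fold)
    })
    if (!any(vapply(maps, is.null, TRUE)))
      out[[as.character(r)]] <- list(first = maps[[1]], second = maps[[2]])
    else warning("run ", r, " skipped in per-half orientation mapping")
  }
  out
}

#' Reduce translation data for the data-amount control analysis
#'
#' Two reduction modes mirroring the control analyses that equate data
#' amounts between groups: `truncate_runs` discards trailing events of
#' each run until the retained translation time is at most `fraction`
#' of the original (closest from below; run durations are shortened to
#' the end of the last retained event); `truncate_translations` keeps
#' all events but multiplies every translation duration by `fraction`
#' (onsets unchanged), modeling only the first part of each phase.
#'
#' @param events an `event_table`.
#' @param fraction retained fraction of translation data, in (0, 1];
#'   0.8016 is the ratio used to match the older adults' data amount.
#' @param mode `"truncate_runs"` or `"truncate_translations"`.
#' @return a reduced `event_table` (attributes updated accordingly).
#' @export
reduce_data <- function(events, fraction = 0.8016,
                        mode = c("truncate_runs", "truncate_translations")) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(events)
  run_dur <- attr(events, "run_durations")
  if (mode == "truncate_translations") {
    out <- events
    sel <- out$kind == "translation"
    out$duration[sel] <- out$duration[sel] * fraction
    return(out)
  }
  keep <- logical(nrow(events))
  new_dur <- run_dur
  for (r in unique(events$run_id)) {
    idx <- which(events$run_id == r)
    e <- events[idx, ]
    tdur <- ifelse(e$kind == "translation", e$duration, 0)
    total <- sum(tdur)
    cum <- cumsum(tdur)
    k <- max(which(cum <= fraction * total + 1e-12))
    keep[idx[seq_len(k)]] <- TRUE
    new_dur[[as.character(r)]] <- e$onset[k] + e$duration[k]
  }
  out <- events[keep, , drop = FALSE]
  attr(out, "run_durations") <- new_dur
  class(out) <- class(events)
  out
}

#' Signal-quality metrics: tSNR and head-motion summaries
#'
#' tSNR is each voxel's temporal mean divided by its temporal SD,
#' averaged over the ROI (voxels with zero temporal SD are excluded
#' with a warning). Framewise linear displacement is
#' `|dx| + |dy| + |dz|` between successive scans, averaged over scans
#' and runs; angular displacement likewise for yaw + pitch + roll.
#'
#' @param ts a `voxel_ts`.
#' @return list with `tsnr`, `mean_linear_disp` (mm per scan) and
#'   `mean_angular_disp` (deg per scan).
#' @export
quality_metrics <- function(ts) {
  sig <- do.call(cbind, lapply(ts$runs, function(r) r$signal))
  if (ncol(sig) < 2) stop("need at least 2 scans")
  m <- rowMeans(sig)
  s <- apply(sig, 1, stats::sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " voxel(s) with zero temporal SD excluded from tSNR")
    m <- m[s > 0]; s <- s[s > 0]
  }
  disp <- vapply(ts$runs, function(r) {
    d <- abs(diff(r$motion))
    c(lin = mean(rowSums(d[, 1:3, drop = FALSE])),
      ang = mean(rowSums(d[, 4:6, drop = FALSE])))
  }, c(lin = 0, ang = 0))
  list(tsnr = mean(m / s),
       mean_linear_disp = mean(disp["lin", ]),
       mean_angular_disp = mean(disp["ang", ]))
}
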