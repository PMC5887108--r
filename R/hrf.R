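#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking at 6 s minus an
#' undershoot gamma peaking at 16 s scaled by 1/6, evaluated at time `t`
#' (seconds after stimulus onset). The kernel is normalized to unit peak
#' so that regressor heights keep the units of the event weights.
#'
#' @param t time in seconds (vector).
#' @param peak_delay delay of response peak (s), default 6.
#' @param undershoot_delay delay of undershoot (s), default 16.
#' @param ratio response/undershoot amplitude ratio, default 6.
#' @return HRF values at `t`.
#' @export
#' @examples
#' t <- seq(0, 32, 0.1)
#' h <- canonical_hrf(t)
#' t[which.max(h)]  # ~5 s (mode of the difference kernel)
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(h)
}

# Build an HRF-convolved regressor sampled at scan times.
#
# onsets/durations in seconds, heights are per-event weights (boxcar
# amplitude). The boxcar is built on a high-resolution grid (dt seconds;
# the same grid is used by the forward simulator and the analysis, so
# quantization cancels in recovery),
# convolved with the canonical HRF, and sampled at scan acquisition times
# (i - 1) * TR for i = 1..n_scans. This is the single convolution
# primitive shared by the forward BOLD simulator and the design-matrix
# builder, so that planted signals are exactly within the span of the
# fitted design in noiseless data.
convolve_events <- function(onsets, durations, heights, n_scans, tr,
                            dt = 0.25, hrf_length = 32) {
  stopifnot(length(onsets) == length(durations),
            length(onsets) == length(heights), tr > 0)
  t_end <- n_scans * tr
  n_hi <- ceiling(t_end / dt) + 1L
  box <- numeric(n_hi)
  if (length(onsets)) {
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] / dt) + 1L
      i1 <- min(ceiling((onsets[k] + durations[k]) / dt), n_hi)
      if (i1 >= i0) box[i0:i1] <- box[i0:i1] + heights[k]
    }
  }
  # FFT convolution on a power-of-two length (cached kernel transform);
  # stats::convolve pads to n + m - 1, which can be a near-prime length
  # with catastrophic FFT cost
  n_kern <- length(seq(0, hrf_length, by = dt))
  N <- stats::nextn(n_hi + n_kern - 1L, 2)
  key <- sprintf("%d_%g_%g", N, dt, hrf_length)
  kf <- .hrf_fft_cache[[key]]
  if (is.null(kf)) {
    kern <- canonical_hrf(seq(0, hrf_length, by = dt))
    kf <- stats::fft(c(kern, numeric(N - n_kern)))
    .hrf_fft_cache[[key]] <- kf
  }
  conv <- Re(stats::fft(stats::fft(c(box, numeric(N - n_hi))) * kf,
                        inverse = TRUE))[seq_len(n_hi)] / N * dt
  scan_idx <- pmin(floor(((seq_len(n_scans) - 1L) * tr) / dt) + 1L, n_hi)
  conv[scan_idx]
}

.hrf_fft_cache <- new.env(parent = emptyenv())
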