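#' Circular utilities for periodic orientation data
#'
#' Grid orientations from an n-fold directional model live on a periodic
#' domain of `360/n` degrees (60 degrees for the hexadirectional model).
#' These helpers implement wrapping, signed and absolute circular
#' differences, the mean resultant length, and Rayleigh's test for
#' non-uniformity, all in degrees.
#'
#' @name circular
#' @keywords internal
NULL

#' Wrap angles into a periodic domain
#'
#' @param x angles in degrees.
#' @param period domain period in degrees (default 360).
#' @return angles wrapped into `[0, period)`.
#' @export
#' @examples
#' wrap_deg(c(-90, 370))        # 270, 10
#' wrap_deg(61, period = 60)    # 1
wrap_deg <- function(x, period = 360) {
  out <- x %% period
  # guard against -1e-18 %% 60 == 60 style round-off
  out[out >= period] <- 0
  out
}

#' Absolute circular difference between two angle sets
#'
#' On a domain with the given period, the largest possible absolute
#' difference is `period / 2` (30 degrees for the 60-degree orientation
#' domain of the 6-fold model).
#'
#' @param a,b angles in degrees.
#' @param period domain period in degrees.
#' @return absolute circular differences in `[0, period/2]`.
#' @export
#' @examples
#' circ_diff_deg(2, 58, period = 60)  # 4
circ_diff_deg <- function(a, b, period = 360) {
  d <- abs(wrap_deg(a, period) - wrap_deg(b, period))
  pmin(d, period - d)
}

#' Circular mean of angles in degrees
#'
#' @param x angles in degrees on the full circle.
#' @return circular mean in `[0, 360)`.
#' @export
circ_mean_deg <- function(x) {
  th <- x * pi / 180
  wrap_deg(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

#' Mean resultant length of angles in degrees
#'
#' @param x angles in degrees on the full circle.
#' @return mean resultant length R in `[0, 1]`.
#' @export
resultant_length <- function(x) {
  th <- x * pi / 180
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Computes z = n * R^2 with R the mean resultant length, and the
#' Wilkie/Zar small-sample approximation to the p value:
#' p = exp(-z) * (1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288n^2)),
#' clamped to [0, 1].
#'
#' @param x angles in degrees on the full circle.
#' @return list with `z`, `p`, `R` and `n`.
#' @export
rayleigh_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("rayleigh_test() needs at least 2 angles")
  R <- resultant_length(x)
  z <- n * R^2
  p <- exp(-z) *
    (1 + (2 * z - z^2) / (4 * n) -
       (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p = min(max(p, 0), 1), R = R, n = n)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used for heading noise in the
#' path-integration agent. `kappa = Inf` returns exact zeros (no noise).
#'
#' @param n number of draws.
#' @param kappa concentration parameter (> 0, or Inf).
#' @return `n` draws in radians, centered on 0, in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  stopifnot(kappa > 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Run code with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds below 2^31 from one integer seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
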