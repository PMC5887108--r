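#' Correction factors from standardization-path responses
#'
#' Each participant's verbal distance estimates are corrected for their
#' individual sense of "a meter" using straight standardization walks of
#' 3 m and 9 m: responses of the same distance and modality are
#' averaged, and the correction factor is f = d_correct / d_response.
#' The 3 m paths yield the factor for shorter distances, the 9 m paths
#' the factor for longer distances.
#'
#' @param records data.frame of standardization responses with columns
#'   `modality`, `std_distance` (3 or 9) and `response` (m, > 0).
#' @param modality which modality to compute factors for.
#' @param threshold raw-response threshold (m) separating use of the
#'   short vs long factor downstream.
#' @return a `correction_factors` list: `f_short`, `f_long`,
#'   `threshold`, `modality`.
#' @export
#' @examples
#' rec <- data.frame(modality = "visual", std_distance = c(3, 3, 9, 9),
#'                   response = c(6, 6, 8, 10))
#' compute_correction_factors(rec, "visual")  # f_short 0.5, f_long 1
compute_correction_factors <- function(records, modality, threshold = 6) {
  r <- records[records$modality == modality, , drop = FALSE]
  if (any(!is.finite(r$response) | r$response <= 0))
    stop("invalid standardization response (must be finite and > 0)")
  f_for <- function(d) {
    resp <- r$response[r$std_distance == d]
    if (!length(resp)) stop("no ", d, " m standardization responses for ",
                            modality)
    d / mean(resp)
  }
  structure(list(f_short = f_for(3), f_long = f_for(9),
                 threshold = threshold, modality = modality),
            class = "correction_factors")
}

#' Standardize a responded distance
#'
#' Raw responses between 0 and 6 m (inclusive) are multiplied by the
#' short-distance factor, responses above 6 m by the long-distance
#' factor.
#'
#' @param d_response responded distance(s) in meters, >= 0.
#' @param factors a [compute_correction_factors()] result.
#' @return standardized distance(s) in meters.
#' @export
standardize_distance <- function(d_response, factors) {
  stopifnot(all(d_response >= 0))
  ifelse(d_response <= factors$threshold,
         d_response * factors$f_short,
         d_response * factors$f_long)
}

#' Score one path traversal: incremental presumed-start errors
#'
#' At each stopping point k the responded (standardized) distance and
#' bearing define a presumed starting point
#' `presumed_k = stop_k + d_std * (cos(ori), sin(ori))`. The path
#' integration error at stop k is the Euclidean distance between
#' `presumed_k` and `presumed_(k-1)`, where `presumed_0` is the true
#' starting point — so each error reflects only the incremental error
#' accrued on the latest path segment.
#'
#' @param path a `path_spec`.
#' @param records data.frame of the traversal's 3 responses, columns
#'   `stop` (1..3), `response` (m) and `bearing` (deg, arena frame,
#'   counterclockwise from +x).
#' @param factors [compute_correction_factors()] result for this
#'   participant and modality.
#' @return numeric length-3 vector of nonnegative incremental errors (m).
#' @export
score_path <- function(path, records, factors) {
  records <- records[order(records$stop), , drop = FALSE]
  if (!identical(as.integer(records$stop), 1:3))
    stop("need exactly one response per stopping point 1..3")
  d_std <- standardize_distance(records$response, factors)
  th <- records$bearing * pi / 180
  presumed <- path$stopping_points + d_std * cbind(cos(th), sin(th))
  prev <- rbind(path$start, presumed[-3, , drop = FALSE])
  sqrt(rowSums((presumed - prev)^2))
}

#' Aggregate path-integration errors into a per-modality summary
#'
#' Mean incremental error over all stopping points of all traversals of
#' one modality; performance is the reciprocal of the mean error
#' (undefined — `NA` — when the mean error is 0).
#'
#' @param errors numeric vector of per-stop incremental errors (m) for
#'   one modality (concatenated over traversals).
#' @param modality label stored in the summary.
#' @return a `pi_summary` list: `modality`, `mean_error`,
#'   `performance`, `n_stops`, `errors`.
#' @export
aggregate_errors <- function(errors, modality = NA_character_) {
  if (!length(errors)) stop("no scored stops")
  stopifnot(all(errors >= 0))
  m <- mean(errors)
  structure(list(modality = modality, mean_error = m,
                 performance = if (m > 0) 1 / m else NA_real_,
                 n_stops = length(errors), errors = errors),
            class = "pi_summary")
}

#' Simulate path-integration responses for one agent and modality
#'
#' Traverses every normal path of the given modality in the session
#' design and responds at each of the three stopping points. The
#' agent's responded distance is the true distance to the start times
#' the path-integration gain, the verbal scale, and mean-one lognormal
#' noise; the responded bearing is the true bearing plus von Mises
#' noise. Standardization paths are "walked straight", so their
#' responses carry the verbal scale (and distance noise) but not the
#' path-integration gain — which is exactly the component the
#' standardization correction is designed to remove.
#'
#' @param paths list of 8 `path_spec`s.
#' @param agent an [agent_profile()].
#' @param modality `"body_based"` or `"visual"`.
#' @param seed RNG seed.
#' @param session a [build_session()] design (default design ships with
#'   a fixed seed shared by all simulated participants).
#' @return a `pi_records` data.frame with one row per response:
#'   `modality`, `type`, `path_id`, `repetition`, `stop`,
#'   `std_distance`, `true_distance`, `true_bearing`, `response`,
#'   `bearing`.
#' @export
simulate_pi_responses <- function(paths, agent, modality, seed = 1,
                                  session = build_session(paths)) {
  stopifnot(inherits(agent, "agent_profile"))
  if (!modality %in% c("body_based", "visual"))
    stop("modality must be 'body_based' or 'visual'")
  sdlog <- sqrt(log(1 + agent$distance_noise_cv^2))
  noise_mult <- function(n) {
    if (sdlog == 0) rep(1, n)
    else exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  with_seed(seed, {
    des <- session[session$modality == modality, , drop = FALSE]
    is_std <- des$type == "standardization"
    n_per <- ifelse(is_std, 1L, 3L)
    idx <- rep(seq_len(nrow(des)), n_per)
    stop_no <- unlist(lapply(n_per, seq_len))
    stop_no[is_std[idx]] <- NA_integer_
    d0 <- b0 <- numeric(length(idx))
    for (i in which(!is_std)) {
      path <- paths[[des$path_id[i]]]
      rel <- sweep(path$stopping_points, 2, path$start)  # stop - start
      d0[idx == i] <- sqrt(rowSums(rel^2))
      b0[idx == i] <- wrap_deg(atan2(-rel[, 2], -rel[, 1]) * 180 / pi)
    }
    d0[is_std[idx]] <- des$std_distance[idx][is_std[idx]]
    b0[is_std[idx]] <- NA_real_
    gain <- ifelse(is_std[idx], 1, agent$distance_gain)  # straight walks
    resp <- d0 * gain * agent$verbal_scale * noise_mult(length(idx))
    bear <- wrap_deg(b0 + rvonmises(length(idx), agent$heading_kappa) *
                       180 / pi)
    bear[is_std[idx]] <- NA_real_
    out <- data.frame(
      modality = modality, type = des$type[idx],
      path_id = des$path_id[idx], repetition = des$repetition[idx],
      stop = stop_no,
      std_distance = ifelse(is_std[idx], des$std_distance[idx], NA_real_),
      true_distance = d0, true_bearing = b0, response = resp,
      bearing = bear)
    class(out) <- c("pi_records", "data.frame")
    out
  })
}

#' Score a full set of simulated or recorded PI responses
#'
#' Computes correction factors from the standardization rows, scores
#' every traversal with [score_path()], and aggregates per modality.
#'
#' @param records a `pi_records` data.frame (possibly both modalities).
#' @param paths the path set the records refer to.
#' @return named list of `pi_summary` per modality present.
#' @export
score_pi_records <- function(records, paths) {
  std <- records[records$type == "standardization", , drop = FALSE]
  out <- list()
  for (mod in unique(records$modality)) {
    factors <- compute_correction_factors(std, mod)
    pr <- records[records$type == "path" & records$modality == mod, ,
                  drop = FALSE]
    errs <- unlist(lapply(split(pr, list(pr$path_id, pr$repetition),
                                drop = TRUE), function(tr) {
      score_path(paths[[tr$path_id[1]]], tr, factors)
    }))
    out[[mod]] <- aggregate_errors(unname(errs), mod)
  }
  out
}
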