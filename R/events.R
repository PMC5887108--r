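#' Construct an event table
#'
#' The event table is the timestamped record of a scanning run:
#' one row per event with columns `run_id`, `trial_id`, `onset` (s),
#' `duration` (s), `kind` (one of translation, rotation, stationary,
#' cue, feedback) and, for translation events only, `direction`
#' (degrees in `[0, 360)`, counterclockwise from +x).
#'
#' @param df data.frame with the columns above (`trial_id` optional).
#' @param run_durations named or ordered numeric vector of run durations
#'   in seconds (one per unique `run_id`).
#' @return a validated `event_table` (data.frame subclass).
#' @export
make_event_table <- function(df, run_durations) {
  if (is.null(df$trial_id)) df$trial_id <- NA_integer_
  if (is.null(df$direction)) df$direction <- NA_real_
  df <- df[, c("run_id", "trial_id", "onset", "duration", "kind", "direction")]
  runs <- sort(unique(df$run_id))
  if (is.null(names(run_durations)))
    names(run_durations) <- as.character(runs)
  out <- structure(df, run_durations = run_durations,
                   class = c("event_table", "data.frame"))
  validate_event_table(out)
  out
}

#' Validate an event table
#'
#' Checks the structural invariants: onsets nondecreasing within each
#' run, no overlapping events within a run, every translation row has a
#' finite direction in `[0, 360)`, and all events end within their run.
#'
#' @param events an `event_table`.
#' @return the table, invisibly; stops with a field-naming message on
#'   violation.
#' @export
validate_event_table <- function(events) {
  kinds <- c("translation", "rotation", "stationary", "cue", "feedback")
  if (!all(events$kind %in% kinds))
    stop("invalid event kind: ", paste(setdiff(events$kind, kinds), collapse = ", "))
  rd <- attr(events, "run_durations")
  for (r in unique(events$run_id)) {
    e <- events[events$run_id == r, ]
    if (is.unsorted(e$onset)) stop("onsets not nondecreasing in run ", r)
    if (nrow(e) > 1 &&
        any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping events in run ", r)
    if (!is.null(rd) && any(e$onset + e$duration > rd[[as.character(r)]] + 1e-6))
      stop("event extends past run duration in run ", r)
  }
  tr <- events[events$kind == "translation", ]
  if (any(!is.finite(tr$direction)) ||
      any(tr$direction < 0 | tr$direction >= 360))
    stop("translation rows must have finite direction in [0, 360)")
  invisible(events)
}

#' Simulate a navigation session of the object-location memory task
#'
#' Generates the event stream of a session in the square virtual arena:
#' repeated trials of cue -> navigate (alternating rotation and straight
#' translation segments; translational and rotational movement never
#' overlap) -> confirm -> feedback, with a teleport to a random position
#' between trials (teleports produce no translation event). Translation
#' events are straight segments with one constant direction each; the
#' direction equals the bearing of the logged displacement.
#'
#' @param arena an [arena_config()].
#' @param n_runs number of scanning runs.
#' @param run_duration run duration in seconds (default 960, i.e. 16 min).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param cue_duration,feedback_duration event durations in seconds.
#' @param min_segment minimum translation segment length in vm (keeps
#'   all translation events comfortably above 1 s at 15 vm/s).
#' @param aim_sd SD in vm of the response scatter around the true object
#'   location (drives the trial error distances).
#' @return an `event_table` with attributes `run_durations`,
#'   `trajectory` (per-translation displacement log with start/end
#'   coordinates) and `trials` (per-trial error distances in vm).
#' @export
#' @examples
#' ev <- simulate_navigation_session(arena_config(), n_runs = 1,
#'                                   run_duration = 120, seed = 1)
#' table(ev$kind)
simulate_navigation_session <- function(arena = arena_config(), n_runs = 4,
                                        run_duration = 960, seed = 1,
                                        cue_duration = 2,
                                        feedback_duration = 1.5,
                                        min_segment = 16, aim_sd = 6) {
  if (!inherits(arena, "arena_config")) stop("arena must be an arena_config")
  if (run_duration <= 0) stop("run_duration must be > 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  side <- arena$side_length
  with_seed(seed, {
    # objects drawn centrally with their centroid recentred on the
    # arena midpoint: keeps translation directions near-isotropic, as
    # the directional GLMs require for balanced direction sampling
    objects <- cbind(stats::runif(arena$n_objects, 0.25 * side, 0.75 * side),
                     stats::runif(arena$n_objects, 0.25 * side, 0.75 * side))
    objects <- sweep(objects, 2, colMeans(objects) - side / 2)
    objects <- pmin(pmax(objects, 0.1 * side), 0.9 * side)
    acc <- list(run = list(), trial = list(), kind = list(), dur = list(),
                dir = list(), onset = list())
    traj <- list(); trials <- list()
    for (run in seq_len(n_runs)) {
      t <- 0; trial <- 0L
      pos <- stats::runif(2, 0, side)
      heading <- stats::runif(1, 0, 360)
      while (TRUE) {
        trial <- trial + 1L
        kind <- "cue"; dur <- cue_duration; dir <- NA_real_
        tj <- NULL
        obj <- objects[sample.int(nrow(objects), 1L), ]
        target <- pmin(pmax(obj + stats::rnorm(2, 0, aim_sd), 2), side - 2)
        # waypoints: possibly one intermediate point, then the target
        wps <- if (stats::runif(1) < 0.4) {
          mid <- (pos + target) / 2 + stats::rnorm(2, 0, 0.15 * side)
          mid <- pmin(pmax(mid, 2), side - 2)
          if (sqrt(sum((mid - pos)^2)) >= min_segment &&
              sqrt(sum((target - mid)^2)) >= min_segment)
            list(mid, target) else list(target)
        } else list(target)
        p <- pos
        for (w in wps) {
          d <- sqrt(sum((w - p)^2))
          if (d < min_segment) next
          wdir <- wrap_deg(atan2(w[2] - p[2], w[1] - p[1]) * 180 / pi)
          turn <- circ_diff_deg(wdir, heading)
          if (turn > 1) {
            kind <- c(kind, "rotation")
            dur <- c(dur, turn / arena$rotation_speed)
            dir <- c(dir, NA_real_)
          }
          heading <- wdir
          kind <- c(kind, "translation")
          dur <- c(dur, d / arena$move_speed)
          dir <- c(dir, wdir)
          tj <- rbind(tj, c(run, trial, NA, p[1], p[2], w[1], w[2]))
          p <- w
        }
        kind <- c(kind, "stationary", "feedback")   # confirm pause, feedback
        dur <- c(dur, stats::runif(1, 0.5, 1.5), feedback_duration)
        dir <- c(dir, NA_real_, NA_real_)
        onset <- t + cumsum(c(0, dur[-length(dur)]))
        if (t + sum(dur) > run_duration) break  # trial does not fit: end run
        t <- t + sum(dur)
        i <- length(acc$run) + 1L
        acc$run[[i]] <- rep(run, length(kind))
        acc$trial[[i]] <- rep(trial, length(kind))
        acc$kind[[i]] <- kind; acc$dur[[i]] <- dur; acc$dir[[i]] <- dir
        acc$onset[[i]] <- onset
        if (!is.null(tj)) {
          tj[, 3] <- onset[kind == "translation"]
          traj[[length(traj) + 1L]] <- tj
        }
        trials[[length(trials) + 1L]] <-
          c(run, trial, sqrt(sum((p - obj)^2)))
        pos <- stats::runif(2, 0, side)   # teleport (no translation event)
        heading <- stats::runif(1, 0, 360)
      }
    }
    df <- data.frame(run_id = unlist(acc$run), trial_id = unlist(acc$trial),
                     onset = unlist(acc$onset), duration = unlist(acc$dur),
                     kind = unlist(acc$kind), direction = unlist(acc$dir))
    out <- make_event_table(df,
                            stats::setNames(rep(run_duration, n_runs),
                                            seq_len(n_runs)))
    tr_log <- as.data.frame(do.call(rbind, traj))
    names(tr_log) <- c("run_id", "trial_id", "onset", "x0", "y0", "x1", "y1")
    tr_df <- as.data.frame(do.call(rbind, trials))
    names(tr_df) <- c("run_id", "trial_id", "error_distance")
    attr(out, "trajectory") <- tr_log
    attr(out, "trials") <- tr_df
    attr(out, "arena") <- arena
    attr(out, "objects") <- objects
    out
  })
}
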