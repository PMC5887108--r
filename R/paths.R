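#' Build a curved path-integration path from a 3-legged template
#'
#' A 3-legged path is dead-reckoned from three leg lengths (each 2, 3, 4
#' or 5 m) and two signed turning angles (each +/-55, +/-80 or +/-105
#' degrees; positive = left). A natural interpolating cubic spline
#' through the four waypoints (start, two turning points, end) with
#' centripetal (square-root chord length) parameterization turns the
#' legs into a corner-free curve, emulating the cscvn-style spline
#' construction. The three stopping points sit on the curve at the
#' first turn, the second turn, and the path end. The whole curve must
#' fit a 10 x 6 m room (checked on the rotation-free bounding box:
#' longer extent at most 10 m, shorter at most 6 m).
#'
#' @param leg_lengths numeric length-3, leg lengths in meters from
#'   `{2, 3, 4, 5}`.
#' @param turn_angles numeric length-2, signed turn angles in degrees
#'   with magnitudes from `{55, 80, 105}`.
#' @param n_samples number of samples of the curve.
#' @param parameterization `"centripetal"` (default) or `"chordal"`.
#' @param check_menu enforce the stated leg/angle menus (disable for
#'   degenerate test-only templates).
#' @param check_bounds enforce the 10 x 6 m room fit.
#' @return a `path_spec`: list with `waypoints` (4 x 2), `curve`
#'   (n_samples x 2, arc-length ordered), `arc_length`,
#'   `stopping_points` (3 x 2), `start`, `leg_lengths`, `turn_angles`.
#' @export
#' @examples
#' p <- build_path(c(3, 4, 5), c(80, -80))
#' p$stopping_points
build_path <- function(leg_lengths, turn_angles, n_samples = 400,
                       parameterization = c("centripetal", "chordal"),
                       check_menu = TRUE, check_bounds = check_menu) {
  parameterization <- match.arg(parameterization)
  stopifnot(length(leg_lengths) == 3, length(turn_angles) == 2)
  if (check_menu) {
    if (!all(leg_lengths %in% c(2, 3, 4, 5)))
      stop("leg lengths must be 2, 3, 4 or 5 m")
    if (!all(abs(turn_angles) %in% c(55, 80, 105)))
      stop("turn angles must be +/-55, +/-80 or +/-105 degrees")
  }
  heading <- 0
  wp <- matrix(0, 4, 2)
  for (i in 1:3) {
    wp[i + 1, ] <- wp[i, ] + leg_lengths[i] *
      c(cos(heading * pi / 180), sin(heading * pi / 180))
    if (i < 3) heading <- heading + turn_angles[i]
  }
  chord <- sqrt(rowSums(diff(wp)^2))
  tk <- c(0, cumsum(if (parameterization == "centripetal")
    sqrt(chord) else chord))
  fx <- stats::splinefun(tk, wp[, 1], method = "natural")
  fy <- stats::splinefun(tk, wp[, 2], method = "natural")
  tt <- sort(unique(c(seq(0, max(tk), length.out = n_samples), tk)))
  curve <- cbind(x = fx(tt), y = fy(tt))
  seg <- sqrt(rowSums(diff(curve)^2))
  ext <- sort(c(diff(range(curve[, 1])), diff(range(curve[, 2]))),
              decreasing = TRUE)
  if (check_bounds && (ext[1] > 10 + 1e-6 || ext[2] > 6 + 1e-6))
    stop(sprintf(paste0("path (legs %s; angles %s) does not fit a ",
                        "10 x 6 m room: extent %.2f x %.2f m"),
                 paste(leg_lengths, collapse = ","),
                 paste(turn_angles, collapse = ","), ext[1], ext[2]))
  stops <- rbind(wp[2, ], wp[3, ], wp[4, ])
  colnames(stops) <- c("x", "y")
  structure(list(waypoints = wp, curve = curve, t = tt,
                 arc_length = sum(seg), stopping_points = stops,
                 start = wp[1, ], leg_lengths = leg_lengths,
                 turn_angles = turn_angles,
                 parameterization = parameterization),
            class = "path_spec")
}

#' The shipped set of eight path templates
#'
#' Eight leg/angle combinations from the stated menus, counterbalanced
#' in turn direction (two of each left/left, left/right, right/left,
#' right/right pattern) and all fitting the 10 x 6 m room. The original
#' study's exact combinations are not printed in the main text; this
#' set is a valid, clearly synthetic stand-in with the same design
#' constraints.
#'
#' @return named list of 8 `path_spec`s (`path1` ... `path8`).
#' @export
default_path_set <- function() {
  templates <- list(
    list(l = c(3, 4, 5), a = c( 80, -80)),
    list(l = c(2, 4, 4), a = c( 55, -105)),
    list(l = c(4, 3, 2), a = c(-80,  80)),
    list(l = c(5, 2, 3), a = c(-55,  105)),
    list(l = c(3, 3, 4), a = c( 105,  55)),
    list(l = c(2, 3, 3), a = c( 55,  80)),
    list(l = c(4, 2, 5), a = c(-105, -55)),
    list(l = c(3, 2, 4), a = c(-55,  -80))
  )
  out <- lapply(templates, function(tp) build_path(tp$l, tp$a))
  names(out) <- paste0("path", seq_along(out))
  out
}

#' Build the 32-traversal session design
#'
#' Traversal order for one session: 32 normal traversals (8 paths x 2
#' repetitions x 2 modalities) in two blocks of 16, pseudo-randomized
#' under the constraint that two occurrences of the same path (in
#' either modality) are separated by at least three different
#' intervening paths. In the middle of each block sit 4 standardization
#' paths in the fixed order 9m_visual, 3m_body-based, 9m_body-based,
#' 3m_visual. A fixed default seed ships so that all synthetic
#' participants share one order, as in the original design.
#'
#' @param paths list of 8 `path_spec`s (default [default_path_set()]).
#' @param seed integer seed for the pseudo-randomization.
#' @param max_tries resampling attempts before giving up.
#' @return a `session_design` data.frame with columns `order`, `block`,
#'   `type` (`path`/`standardization`), `path_id`, `modality`
#'   (`body_based`/`visual`), `repetition`, `std_distance` (3 or 9 m
#'   for standardization rows, `NA` otherwise).
#' @export
build_session <- function(paths = default_path_set(), seed = 20180402,
                          max_tries = 5000) {
  if (length(paths) != 8) stop("need exactly 8 paths")
  ids <- names(paths)
  with_seed(seed, {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      trav <- do.call(rbind, lapply(1:2, function(block) {
        pool <- expand.grid(path_id = ids,
                            modality = c("body_based", "visual"),
                            stringsAsFactors = FALSE)
        pool <- pool[sample.int(nrow(pool)), ]
        pool$block <- block
        pool
      }))
      if (session_spacing_ok(trav$path_id)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy the path-spacing constraint")
    trav$repetition <- stats::ave(seq_len(nrow(trav)), trav$path_id,
                                  trav$modality, FUN = seq_along)
    std <- data.frame(path_id = NA_character_,
                      modality = rep(c("visual", "body_based",
                                       "body_based", "visual"), 2),
                      block = rep(1:2, each = 4), repetition = NA_integer_,
                      std_distance = rep(c(9, 3, 9, 3), 2))
    cols <- c("block", "type", "path_id", "modality", "repetition",
              "std_distance")
    rows <- list()
    for (block in 1:2) {
      tb <- trav[trav$block == block, ]
      sb <- std[std$block == block, ]
      tb$type <- "path"; sb$type <- "standardization"
      tb$std_distance <- NA_real_
      rows[[block]] <- rbind(tb[1:8, cols], sb[, cols], tb[9:16, cols])
    }
    out <- do.call(rbind, rows)
    out$order <- seq_len(nrow(out))
    rownames(out) <- NULL
    structure(out[, c("order", "block", "type", "path_id", "modality",
                      "repetition", "std_distance")],
              class = c("session_design", "data.frame"))
  })
}

# >= 3 distinct other paths strictly between two occurrences of the
# same path (which also implies a positional gap > 3).
session_spacing_ok <- function(path_ids) {
  for (p in unique(path_ids)) {
    pos <- which(path_ids == p)
    for (k in seq_len(length(pos) - 1)) {
      between <- path_ids[seq(pos[k] + 1L, pos[k + 1] - 1L)]
      if (pos[k + 1] - pos[k] <= 3 || length(unique(between)) < 3)
        return(FALSE)
    }
  }
  TRUE
}
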