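test_that("correction factors follow the printed averaging rule", {
  f1 <- compute_correction_factors(unit_std(), "body_based")
  expect_equal(f1$f_short, 1)
  expect_equal(f1$f_long, 1)
  rec <- data.frame(modality = "visual", std_distance = c(3, 3, 9, 9),
                    response = c(6, 6, 8, 10))
  f2 <- compute_correction_factors(rec, "visual")
  expect_equal(f2$f_short, 0.5)      # 3 / mean(6, 6)
  expect_equal(f2$f_long, 1)         # 9 / mean(8, 10)
  bad <- data.frame(modality = "visual", std_distance = 3, response = -1)
  expect_error(compute_correction_factors(bad, "visual"), "invalid")
})

test_that("the 6 m boundary uses the short-distance factor", {
  f <- structure(list(f_short = 0.5, f_long = 2, threshold = 6,
                      modality = "x"), class = "correction_factors")
  expect_equal(standardize_distance(6.0, f), 3.0)
  expect_equal(standardize_distance(6.01, f), 12.02)
  expect_equal(standardize_distance(c(0, 2, 10), f), c(0, 1, 20))
  fid <- compute_correction_factors(unit_std(), "body_based")
  d <- c(0.3, 4, 6, 6.5, 11)
  expect_equal(standardize_distance(d, fid), d)
})

test_that("incremental errors follow the presumed-start geometry", {
  # straight test-only path along +x with stop1 at (3, 0)
  p <- build_path(c(3, 4, 5), c(0, 0), check_menu = FALSE)
  fid <- compute_correction_factors(unit_std(), "body_based")
  # perfect responses: distance and bearing to the true start
  rel <- sweep(p$stopping_points, 2, p$start)
  perfect <- data.frame(stop = 1:3, response = sqrt(rowSums(rel^2)),
                        bearing = wrap_deg(atan2(-rel[, 2], -rel[, 1]) *
                                             180 / pi))
  expect_equal(score_path(p, perfect, fid), rep(0, 3), tolerance = 1e-12)
  # stop 1 at (3,0), response 4 m at bearing 180 -> presumed (-1, 0)
  r1 <- perfect
  r1$response[1] <- 4
  r1$bearing[1] <- 180
  e1 <- score_path(p, r1, fid)
  expect_equal(e1[1], 1)
  # later stops consistent with stop 1's presumed start: incremental
  # errors vanish even though the absolute response is wrong
  presumed1 <- c(-1, 0)
  consistent <- data.frame(stop = 1:3, response = NA_real_,
                           bearing = NA_real_)
  consistent$response[1] <- 4; consistent$bearing[1] <- 180
  for (k in 2:3) {
    v <- presumed1 - p$stopping_points[k, ]
    consistent$response[k] <- sqrt(sum(v^2))
    consistent$bearing[k] <- wrap_deg(atan2(v[2], v[1]) * 180 / pi)
  }
  expect_equal(score_path(p, consistent, fid), c(1, 0, 0),
               tolerance = 1e-12)
  expect_error(score_path(p, perfect[1:2, ], fid), "stopping point")
})

test_that("error aggregation and the performance reciprocal", {
  s <- aggregate_errors(rep(2, 9), "body_based")
  expect_equal(s$mean_error, 2)
  expect_equal(s$performance, 0.5)
  s0 <- aggregate_errors(c(0, 0, 0))
  expect_equal(s0$mean_error, 0)
  expect_true(is.na(s0$performance))
  expect_error(aggregate_errors(numeric(0)), "no scored stops")
})

test_that("a noiseless agent produces zero error end to end", {
  ag <- agent_profile()
  rec <- rbind(
    simulate_pi_responses(the_paths, ag, "body_based", seed = 1,
                          session = the_design),
    simulate_pi_responses(the_paths, ag, "visual", seed = 2,
                          session = the_design))
  s <- score_pi_records(rec, the_paths)
  expect_equal(s$body_based$mean_error, 0, tolerance = 1e-9)
  expect_equal(s$visual$mean_error, 0, tolerance = 1e-9)
})

test_that("verbal scale bias is exactly cancelled by standardization", {
  for (sc in c(0.5, 1, 2, 3.7)) {
    ag <- agent_profile(verbal_scale = sc)
    rec <- simulate_pi_responses(the_paths, ag, "body_based", seed = 1,
                                 session = the_design)
    # raw responses really are scaled
    base <- simulate_pi_responses(the_paths, agent_profile(), "body_based",
                                  seed = 1, session = the_design)
    expect_equal(rec$response, base$response * sc, tolerance = 1e-12)
    s <- score_pi_records(rec, the_paths)
    expect_equal(s$body_based$mean_error, 0, tolerance = 1e-9)
  }
})

test_that("scaling all responses by c > 0 leaves noisy errors unchanged", {
  ag <- agent_profile(distance_noise_cv = 0.2, heading_kappa = 15)
  rec <- simulate_pi_responses(the_paths, ag, "visual", seed = 3,
                               session = the_design)
  s0 <- score_pi_records(rec, the_paths)$visual$mean_error
  # scale chosen so every response stays on its side of the 6 m
  # threshold (the threshold applies to the raw response)
  rec2 <- rec
  rec2$response <- rec$response * 1.02
  same_branch <- all((rec$response <= 6) == (rec2$response <= 6))
  expect_true(same_branch)
  s2 <- score_pi_records(rec2, the_paths)$visual$mean_error
  expect_equal(s2, s0, tolerance = 1e-9)
})

test_that("errors are equivariant under a global frame rotation", {
  ag <- agent_profile(distance_noise_cv = 0.15, heading_kappa = 20)
  rec <- simulate_pi_responses(the_paths, ag, "body_based", seed = 5,
                               session = the_design)
  s0 <- score_pi_records(rec, the_paths)$body_based$mean_error
  rot <- 33
  rotate <- function(xy, d) {
    th <- d * pi / 180
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
    xy %*% t(R)
  }
  paths_r <- lapply(the_paths, function(p) {
    p$waypoints <- rotate(p$waypoints, rot)
    p$curve <- rotate(p$curve, rot)
    p$stopping_points <- rotate(p$stopping_points, rot)
    p$start <- as.numeric(rotate(matrix(p$start, 1), rot))
    p
  })
  rec_r <- rec
  sel <- rec$type == "path"
  rec_r$bearing[sel] <- wrap_deg(rec$bearing[sel] + rot)
  s_r <- score_pi_records(rec_r, paths_r)$body_based$mean_error
  expect_equal(s_r, s0, tolerance = 1e-9)
})

test_that("incremental errors dominate the net displacement", {
  # triangle inequality: the sum of incremental errors bounds the
  # distance between the final presumed start and the true start
  ag <- agent_profile(distance_noise_cv = 0.3, heading_kappa = 6)
  rec <- simulate_pi_responses(the_paths, ag, "body_based", seed = 7,
                               session = the_design)
  fct <- compute_correction_factors(
    rec[rec$type == "standardization", ], "body_based")
  pr <- rec[rec$type == "path", ]
  for (tr in split(pr, list(pr$path_id, pr$repetition), drop = TRUE)) {
    p <- the_paths[[tr$path_id[1]]]
    errs <- score_path(p, tr, fct)
    d3 <- standardize_distance(tr$response[tr$stop == 3], fct)
    th <- tr$bearing[tr$stop == 3] * pi / 180
    presumed3 <- p$stopping_points[3, ] + d3 * c(cos(th), sin(th))
    expect_gte(sum(errs) + 1e-9, sqrt(sum((presumed3 - p$start)^2)))
  }
})

test_that("more heading noise means more error, on average", {
  mean_err <- function(kappa) {
    errs <- vapply(1:40, function(s) {
      ag <- agent_profile(heading_kappa = kappa)
      rec <- simulate_pi_responses(the_paths, ag, "body_based", seed = s,
                                   session = the_design)
      score_pi_records(rec, the_paths)$body_based$mean_error
    }, 0)
    mean(errs)
  }
  errs <- vapply(c(50, 10, 2), mean_err, 0)
  expect_true(all(diff(errs) > 0))
})
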