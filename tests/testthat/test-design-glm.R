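test_that("split at the temporal midpoint partitions scans and events", {
  ev <- tiny_session(seed = 1)               # 240 s runs, TR 1.5: 160 scans
  pg <- planted_grid(n_voxels = 2, phi = 5, spatial_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 2)
  sp <- split_halves(ev, bold)
  for (r in c("1", "2")) {
    expect_length(sp$estimation$scan_idx[[r]], 80)
    expect_length(sp$test$scan_idx[[r]], 80)
  }
  # union of halves reproduces the original event set exactly
  both <- rbind(as.data.frame(sp$estimation$events),
                as.data.frame(sp$test$events))
  both <- both[order(both$run_id, both$onset), ]
  rownames(both) <- NULL
  expect_equal(both, as.data.frame(ev))
})

test_that("an onset exactly at the midpoint goes to the second half", {
  ev <- events_from(c(10, 60, 100), c(2, 2, 2), c(0, 90, 180), 120)
  sp <- split_halves(ev, tr = 1.5)           # midpoint at 60 s
  expect_equal(sp$estimation$events$onset, 10)
  expect_equal(sp$test$events$onset, c(60, 100))
})

test_that("sub-second translations are excluded from the models", {
  ev <- events_from(c(10, 20, 30, 70, 90), c(0.8, 1.0, 2.5, 2, 2),
                    c(0, 45, 90, 10, 20), 120)
  pg <- planted_grid(n_voxels = 1, phi = 5, spatial_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 1)
  d <- build_design_matrix(ev, bold, role = "estimation")
  expect_equal(nrow(d$events_modeled), 2)    # 1.0 s kept, 0.8 s dropped
  expect_equal(d$events_modeled$duration, c(1.0, 2.5))
  ev2 <- events_from(c(10, 20), c(0.5, 0.8), c(0, 45), 120)
  bold2 <- generate_bold(ev2, pg, seed = 1)
  suppressWarnings(   # the one-sided-run warning is expected here too
    expect_error(build_design_matrix(ev2, bold2, role = "estimation"),
                 "no modelable events"))
})

test_that("the aligned modulator collapses as the trigonometry dictates", {
  # all directions equal to phi: aligned weights cos(0) = 1; after the
  # mean-centering of event weights the aligned column vanishes, i.e.
  # the modulator is fully absorbed by the translation main effect.
  # one early event keeps the estimation half non-empty; the modeled
  # test events sit in the second half of the 240 s run
  on1 <- c(10, seq(130, 230, 20))
  ev <- events_from(on1, rep(2, 7), rep(42, 7), 240)
  pg <- planted_grid(n_voxels = 1, phi = 42, spatial_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 1)
  d <- build_design_matrix(ev, bold, phi = 42, role = "test")
  expect_equal(max(abs(d$X[, "aligned"])), 0, tolerance = 1e-12)
  # directions at phi + 15 degrees: cos(6 * 15deg) = cos(90) = 0 weights
  ev2 <- events_from(on1, rep(2, 7), rep(42 + 15, 7), 240)
  d2 <- build_design_matrix(ev2, generate_bold(ev2, pg, seed = 1),
                            phi = 42, role = "test")
  expect_equal(max(abs(d2$X[, "aligned"])), 0, tolerance = 1e-12)
})

test_that("least squares is exact on noiseless data and flags collinearity", {
  ev <- tiny_session(seed = 4, n_runs = 1)
  pg <- planted_grid(n_voxels = 4, phi = 17, spatial_sd = 0,
                     amplitude = 0.7, noise_sd = 0, seed = 2)
  bold <- generate_bold(ev, pg, seed = 3)
  d <- build_design_matrix(ev, bold, role = "estimation")
  f <- fit_glm(bold, d)
  # planted amplitude decomposes into quadrature betas exactly
  expect_equal(unname(sqrt(f$betas[, "sin"]^2 + f$betas[, "cos"]^2)),
               rep(0.7, 4), tolerance = 1e-8)
  d_bad <- d
  d_bad$X <- cbind(d$X, dup = d$X[, "main"])
  expect_error(fit_glm(bold, d_bad), "rank deficient.*dup")
})

test_that("pure-noise voxels give quadrature betas within 3 SE of zero", {
  ev <- tiny_session(seed = 8, n_runs = 1)
  pg <- planted_grid(n_voxels = 40, phi = 0, spatial_sd = 0,
                     amplitude = 0, noise_sd = 1, seed = 5)
  bold <- generate_bold(ev, pg, seed = 6)
  d <- build_design_matrix(ev, bold, role = "estimation")
  f <- fit_glm(bold, d)
  zs <- f$betas[, c("sin", "cos")] / f$se[, c("sin", "cos")]
  # ~2 of 80 z-scores may exceed 3 by chance; the overwhelming majority
  # must not
  expect_gt(mean(abs(zs) < 3), 0.95)
})
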