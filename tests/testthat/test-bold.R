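test_that("the BOLD generator refuses empty translation sets", {
  ev <- events_from(c(0, 10), c(2, 2), NA_real_, 60, kind = "stationary")
  pg <- planted_grid(n_voxels = 2, phi = 10, spatial_sd = 0, seed = 1)
  expect_error(generate_bold(ev, pg), "nothing to modulate")
})

test_that("noiseless planted orientation is recovered exactly", {
  ev <- tiny_session(seed = 2)
  pg <- planted_grid(n_voxels = 3, phi = 23, spatial_sd = 0,
                     amplitude = 1, noise_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 4)
  gr <- crossval_grid_magnitude(bold, ev)
  expect_equal(gr$phi, 23, tolerance = 0.5)
  expect_gt(gr$magnitude, 0)
})

test_that("zero amplitude yields magnitudes centered on zero", {
  mags <- vapply(1:12, function(s) {
    ev <- tiny_session(seed = s)
    pg <- planted_grid(n_voxels = 4, phi = 11, spatial_sd = 0,
                       amplitude = 0, noise_sd = 1, seed = s)
    bold <- generate_bold(ev, pg, seed = s + 100)
    crossval_grid_magnitude(bold, ev)$magnitude
  }, 0)
  se <- sd(mags) / sqrt(length(mags))
  expect_lt(abs(mean(mags)), 3 * se + 1e-12)
})

test_that("ground-truth orientation log matches the drift model", {
  ev <- tiny_session(seed = 6)
  pg <- planted_grid(n_voxels = 50, phi = 30, spatial_sd = 0,
                     p_drift = 0, drift_sd = 0, noise_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 2)
  gt <- attr(bold, "ground_truth")$phi_segments
  expect_equal(dim(gt), c(50, 4))          # 2 runs x 2 halves
  expect_true(all(gt == 30))               # no drift: constant
  pg2 <- planted_grid(n_voxels = 200, phi = 30, spatial_sd = 0,
                      p_drift = 1, drift_sd = 0, noise_sd = 0, seed = 1)
  gt2 <- attr(generate_bold(ev, pg2, seed = 3), "ground_truth")$phi_segments
  # full redraw: later segments uniform, not equal to the first
  expect_true(all(gt2[, 1] == 30))
  expect_gt(mean(gt2[, 2] != 30), 0.99)
})

test_that("full orientation redraw drives temporal stability to chance", {
  ev <- tiny_session(seed = 7)
  pg <- planted_grid(n_voxels = 120, phi = 10, spatial_sd = 0,
                     amplitude = 1.5, p_drift = 1, drift_sd = 0,
                     noise_sd = 0.2, seed = 3)
  bold <- generate_bold(ev, pg, seed = 8)
  st <- stability_summary(bold, ev)
  expect_equal(st$temporal_stability, 0.5, tolerance = 0.12)
})
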