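test_that("fraction 1 is the identity in both reduction modes", {
  ev <- tiny_session(seed = 2)
  expect_equal(as.data.frame(reduce_data(ev, 1, "truncate_runs")),
               as.data.frame(ev))
  expect_equal(as.data.frame(reduce_data(ev, 1, "truncate_translations")),
               as.data.frame(ev))
  expect_error(reduce_data(ev, 0), "fraction")
  expect_error(reduce_data(ev, -0.5), "fraction")
})

test_that("translation truncation scales durations, onsets untouched", {
  ev <- events_from(10, 10, 90, 120)
  red <- reduce_data(ev, 0.8016, "truncate_translations")
  expect_equal(red$duration, 8.016)
  expect_equal(red$onset, 10)
})

test_that("run truncation lands just below the requested fraction", {
  ev <- tiny_session(seed = 3, n_runs = 2, run_duration = 480)
  red <- reduce_data(ev, 0.8016, "truncate_runs")
  for (r in 1:2) {
    orig <- sum(ev$duration[ev$run_id == r & ev$kind == "translation"])
    kept <- sum(red$duration[red$run_id == r & red$kind == "translation"])
    expect_lte(kept / orig, 0.8016 + 1e-9)
    expect_gte(kept / orig, 0.72)
    # run duration shortened to the end of the last retained event
    last <- max(red$onset[red$run_id == r] + red$duration[red$run_id == r])
    expect_equal(attr(red, "run_durations")[[as.character(r)]], last)
  }
  # reduced-data magnitudes agree with the full data on stable signal
  pg <- planted_grid(n_voxels = 6, phi = 12, spatial_sd = 0,
                     amplitude = 1, noise_sd = 0.3, seed = 4)
  bold <- generate_bold(ev, pg, seed = 5)
  full <- crossval_grid_magnitude(bold, ev)$magnitude
  redm <- crossval_grid_magnitude(bold, red)$magnitude
  trm <- crossval_grid_magnitude(bold,
                                 reduce_data(ev, 0.8016,
                                             "truncate_translations"))$magnitude
  expect_equal(redm, full, tolerance = 0.25)
  expect_equal(trm, full, tolerance = 0.25)
})

test_that("tSNR matches a constant-signal oracle", {
  ev <- tiny_session(seed = 5, n_runs = 1)
  pg <- planted_grid(n_voxels = 60, phi = 0, spatial_sd = 0,
                     amplitude = 0, main_amplitude = 0, noise_sd = 1,
                     baseline = 100, seed = 6)
  bold <- generate_bold(ev, pg, seed = 7)
  qm <- quality_metrics(bold)
  expect_equal(qm$tsnr, 100, tolerance = 5)
})

test_that("motion summaries are framewise absolute displacements", {
  ev <- events_from(c(10, 30), c(2, 2), c(0, 90), 60)
  pg <- planted_grid(n_voxels = 2, phi = 0, spatial_sd = 0,
                     noise_sd = 0, seed = 1)
  bold <- generate_bold(ev, pg, seed = 1)
  n <- bold$runs[[1]]$n_scans
  bold$runs[[1]]$motion[] <- 0
  qm0 <- quality_metrics(bold)
  expect_equal(qm0$mean_linear_disp, 0)
  expect_equal(qm0$mean_angular_disp, 0)
  bold$runs[[1]]$motion[, 1] <- rep(c(0, 1), length.out = n)
  qm1 <- quality_metrics(bold)
  expect_equal(qm1$mean_linear_disp, 1)
  # constant voxels are excluded with a warning
  bold$runs[[1]]$signal[1, ] <- 5
  expect_warning(quality_metrics(bold), "zero temporal SD")
})
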