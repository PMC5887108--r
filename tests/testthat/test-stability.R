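test_that("temporal stability handles the canonical cases", {
  m <- map_with(c(1, 10, 25, 40, 59))
  expect_equal(temporal_stability(m, m), 1)
  m30 <- map_with(wrap_deg(m$orientation + 30, 60))
  expect_equal(temporal_stability(m, m30), 0)
  expect_equal(orientation_change(m, m30), 30)
  # the 15-degree boundary is inclusive
  m15 <- map_with(wrap_deg(m$orientation + 15, 60))
  expect_equal(temporal_stability(m, m15), 1)
  expect_error(temporal_stability(m, map_with(c(1, 2))), "voxel sets")
})

test_that("orientation change wraps on the 60-degree domain", {
  m <- map_with(c(0, 10, 20))
  m58 <- map_with(wrap_deg(m$orientation + 58, 60))
  expect_equal(orientation_change(m, m58), 2, tolerance = 1e-10)
  expect_equal(orientation_change(m, m), 0)
})

test_that("stability and change are invariant to a common rotation", {
  set.seed(3)
  a <- map_with(runif(200, 0, 60))
  b <- map_with(runif(200, 0, 60))
  rot <- function(m, d) map_with(wrap_deg(m$orientation + d, 60))
  for (d in c(7, 23.5, 59)) {
    expect_equal(temporal_stability(rot(a, d), rot(b, d)),
                 temporal_stability(a, b))
    expect_equal(orientation_change(rot(a, d), rot(b, d)),
                 orientation_change(a, b), tolerance = 1e-9)
  }
  # consistency: stability is the fraction of voxels with change <= 15
  d <- circ_diff_deg(a$orientation, b$orientation, 60)
  expect_equal(temporal_stability(a, b), mean(d <= 15))
})

test_that("uniform independent maps sit at the analytic chance levels", {
  # |circular difference| on a 60-degree domain is uniform on [0, 30]:
  # E[stable] = 0.5 and E[change] = 15 exactly
  cs <- chance_stability_experiment(n_voxels = 300, reps = 300, seed = 4)
  expect_equal(cs$mean_stability, 0.5, tolerance = 0.01)
  expect_equal(cs$mean_change, 15, tolerance = 0.5)
})

test_that("spatial stability scores coherence on the multiplied circle", {
  expect_equal(spatial_stability(map_with(rep(42, 100)))$rayleigh_z, 100)
  # 30 degrees apart on the 60-degree domain = antipodal after x6
  expect_equal(spatial_stability(map_with(c(10, 40)))$rayleigh_z, 0,
               tolerance = 1e-12)
  expect_error(spatial_stability(map_with(5)), "at least 2")
  # invariant under global rotation, increasing with concentration
  set.seed(5)
  base <- runif(300, 0, 60)
  z0 <- spatial_stability(map_with(base))$rayleigh_z
  zr <- spatial_stability(map_with(wrap_deg(base + 17, 60)))$rayleigh_z
  expect_equal(z0, zr, tolerance = 1e-9)
  zs <- vapply(c(20, 8, 3), function(sd)
    spatial_stability(map_with(wrap_deg(10 + rnorm(300, 0, sd), 60)))$rayleigh_z,
    0)
  expect_true(all(diff(zs) > 0))
})

test_that("uniform orientations give Rayleigh z near one on average", {
  set.seed(6)
  z <- replicate(400, spatial_stability(map_with(runif(200, 0, 60)))$rayleigh_z)
  expect_equal(mean(z), 1, tolerance = 0.1)
})
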