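test_that("the spline interpolates all four waypoints", {
  p <- build_path(c(3, 4, 5), c(80, -80))
  d <- apply(p$waypoints, 1, function(w)
    min(sqrt(rowSums(sweep(p$curve, 2, w)^2))))
  expect_lt(max(d), 1e-6)
  expect_equal(nrow(p$stopping_points), 3)
  expect_equal(unname(p$stopping_points[3, ]), unname(p$waypoints[4, ]))
})

test_that("a degenerate straight template has exact arc length", {
  p <- build_path(c(3, 4, 5), c(0, 0), check_menu = FALSE)
  expect_equal(p$arc_length, 12, tolerance = 1e-6)
})

test_that("all shipped paths fit the 10 x 6 m room", {
  for (p in the_paths) {
    ext <- sort(c(diff(range(p$curve[, 1])), diff(range(p$curve[, 2]))),
                decreasing = TRUE)
    expect_lte(ext[1], 10)
    expect_lte(ext[2], 6)
    expect_true(all(p$leg_lengths %in% 2:5))
    expect_true(all(abs(p$turn_angles) %in% c(55, 80, 105)))
  }
  # turn-direction counterbalancing: 2 of each sign pattern
  pat <- vapply(the_paths, function(p)
    paste(sign(p$turn_angles), collapse = ","), "")
  expect_equal(as.integer(sort(table(pat))), c(2, 2, 2, 2))
  expect_error(build_path(c(5, 5, 5), c(55, -55)), "not fit")
  expect_error(build_path(c(3, 4, 6), c(80, -80)), "leg lengths")
})

test_that("the session design satisfies the study's constraints", {
  trav <- the_design[the_design$type == "path", ]
  expect_equal(nrow(trav), 32)
  expect_equal(as.integer(table(trav$modality)), c(16L, 16L))
  counts <- table(trav$path_id, trav$modality)
  expect_true(all(counts == 2))
  # >= 3 different paths between two occurrences of the same path
  ids <- trav$path_id
  for (p in unique(ids)) {
    pos <- which(ids == p)
    for (k in seq_len(length(pos) - 1)) {
      between <- ids[seq(pos[k] + 1, pos[k + 1] - 1)]
      expect_gte(length(unique(between)), 3)
    }
  }
  # standardization blocks: middle of each 16-block, printed order
  std <- the_design[the_design$type == "standardization", ]
  expect_equal(paste(std$std_distance, std$modality),
               rep(c("9 visual", "3 body_based", "9 body_based",
                     "3 visual"), 2))
  expect_equal(which(the_design$type == "standardization"),
               c(9:12, 29:32))
  # fixed seed: deterministic shared order
  expect_identical(the_design, build_session(the_paths))
})
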