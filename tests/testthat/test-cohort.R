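old_group_r <- function(n_reps, coupling, seed0) {
  spec <- cohort_spec(coupling = coupling)
  vapply(seq_len(n_reps), function(i) {
    seeds <- gridpi:::derive_seeds(seed0 + i, spec$n_old)
    amp <- numeric(spec$n_old); err <- numeric(spec$n_old)
    for (j in seq_len(spec$n_old)) {
      p <- generate_participant(spec, "old", j, seeds[j], the_paths,
                                the_design, with_imaging = FALSE)
      amp[j] <- p$truth$amplitude
      err[j] <- score_pi_records(p$pi_records,
                                 the_paths)$body_based$mean_error
    }
    cor(amp, err)
  }, 0)
}

test_that("cohort structure matches the study design", {
  spec <- cohort_spec(n_runs = 1, run_duration = 180, n_voxels = 4)
  ch <- generate_cohort(spec)
  expect_equal(nrow(ch$covariates), 41)
  expect_equal(as.integer(table(ch$covariates$group)), c(21L, 20L))
  expect_equal(nrow(ch$truth), 41)
  # exactly one older adult lacks neuropsychological scores
  miss <- is.na(ch$covariates$moca)
  expect_equal(sum(miss), 1)
  expect_equal(ch$covariates$group[miss], "old")
  # participants carry events, bold and PI records
  p <- ch$participants[[1]]
  expect_s3_class(p$events, "event_table")
  expect_s3_class(p$pi_records, "pi_records")
  expect_length(p$bold$runs, 1)
  # same spec reproduces the same cohort
  ch2 <- generate_cohort(spec)
  expect_identical(ch$covariates, ch2$covariates)
  expect_identical(ch$truth, ch2$truth)
})

test_that("grid-amplitude coupling plants a negative error association", {
  rs <- old_group_r(100, coupling = TRUE, seed0 = 500)
  expect_gte(mean(rs < 0), 0.95)
})

test_that("without coupling the association is centered on zero", {
  rs <- old_group_r(150, coupling = FALSE, seed0 = 900)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("one replicate of the analyzed cohort shows the age pattern", {
  tab <- cohort_table(cohort_spec(seed = 11))
  young <- tab[tab$group == "young", ]
  old <- tab[tab$group == "old", ]
  expect_lt(mean(old$magnitude), mean(young$magnitude))
  expect_lt(mean(old$temporal_stability), mean(young$temporal_stability))
  # planted old drift p = 0.5: between-half redraw half the time, so
  # planted stability is about 1 - p/2 = 0.75; estimation noise pulls
  # the measured value toward the 0.5 chance level
  expect_equal(mean(old$temporal_stability), 0.75, tolerance = 0.15)
  expect_lt(cor(old$magnitude, old$pi_error_body), 0)
  # the statistical surface runs end to end on the table
  st <- cohort_stats(tab)
  expect_lt(st$group$magnitude$p, 0.05)
  expect_lt(st$correlations$old$body$r, 0)
  expect_equal(sum(st$median_split_old), 21)
  expect_true(all(c("low", "middle", "high") %in%
                    names(st$subgroups_young)))
  expect_equal(st$ancova_error_distance$df2, 38)
  expect_equal(nrow(st$regression$body), 9)
})
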