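test_that("t-test wrappers guard degenerate inputs", {
  expect_error(group_compare(c(1, 1, 1)), "degenerate")
  expect_error(group_compare(1:6, groups = rep(c("a", "b", "c"), 2)),
               "2 levels")
  expect_error(group_compare(c(1, 2), paired_with = c(2, 3)), "degenerate")
  set.seed(1)
  r <- group_compare(c(rnorm(1000), rnorm(1000, 1)),
                     rep(c("a", "b"), each = 1000))
  expect_lt(r$p, 0.001)
  expect_equal(r$df, 1998)              # pooled-variance Student df
  r1 <- group_compare(rnorm(20, 0.5), mu = 0)
  expect_equal(r1$method, "one-sample")
})

test_that("ANCOVA equals the group-coefficient test in the joint model", {
  set.seed(2)
  for (i in 1:10) {
    y <- rnorm(41); g <- rep(c("young", "old"), c(20, 21)); x <- rnorm(41)
    a <- partial_group_effect(y, g, x)
    fit <- summary(stats::lm(y ~ x + factor(g)))
    tg <- fit$coefficients[3, 3]
    expect_equal(a$F, tg^2, tolerance = 1e-8)
    expect_equal(a$df2, 38)
  }
})

test_that("ANCOVA edge behavior matches the algebra", {
  set.seed(3)
  g <- rep(c("a", "b"), each = 30)
  y <- rnorm(60) + (g == "b")
  # outcome fully explained by the covariate: group F collapses
  a0 <- partial_group_effect(y, g, y)
  expect_lt(a0$F, 1e-20)
  # covariate orthogonal to both: F matches the unadjusted F = t^2
  x <- rnorm(60)
  x <- residuals(lm(x ~ y + factor(g)))
  a1 <- partial_group_effect(y, g, x)
  t0 <- group_compare(y, g)$t
  # an exactly orthogonal covariate leaves the group sum of squares
  # untouched; only the error degrees of freedom differ (n-3 vs n-2)
  expect_equal(a1$F, t0^2 * (60 - 3) / (60 - 2), tolerance = 1e-6)
  expect_error(partial_group_effect(y, g, as.numeric(g == "b")),
               "collinear")
})

test_that("planted group effects are detected with power", {
  set.seed(4)
  Fs <- replicate(300, {
    g <- rep(c("a", "b"), c(20, 21))
    y <- rnorm(41) + (g == "b")
    partial_group_effect(y, g, rnorm(41))$F
  })
  expect_gt(mean(Fs), 5)
})

test_that("regression tables recover exact and planted coefficients", {
  set.seed(5)
  x1 <- rnorm(30); x2 <- rnorm(30)
  tabl <- suppressWarnings(   # noiseless outcome: perfect-fit notice
    regression_table(2 * x1, data.frame(x1 = x1, x2 = x2)))
  expect_equal(tabl$beta[tabl$predictor == "x1"], 2, tolerance = 1e-10)
  expect_equal(tabl$beta[tabl$predictor == "x2"], 0, tolerance = 1e-10)
  expect_error(regression_table(rnorm(3),
                                data.frame(a = rnorm(3), b = rnorm(3),
                                           c = rnorm(3))),
               "more observations")
  # missing rows are dropped listwise
  x1[1] <- NA
  t2 <- regression_table(rnorm(30), data.frame(x1 = x1, x2 = x2))
  expect_equal(attr(t2, "n"), 29)
})

test_that("only the planted predictor turns out significant", {
  set.seed(6)
  hits <- replicate(200, {
    p <- as.data.frame(matrix(rnorm(21 * 4), 21))
    y <- 1.2 * p$V1 + rnorm(21, 0, 0.5)
    tabl <- regression_table(y, p)
    c(tabl$p[1] < 0.05, tabl$p[-1] < 0.05)
  })
  expect_gt(mean(hits[1, ]), 0.9)           # planted effect found
  expect_lt(mean(hits[-1, ]), 0.12)         # nulls at nominal rate
})

test_that("null tests reject at the nominal five percent rate", {
  set.seed(7)
  rej <- replicate(2000, {
    g <- rep(c("a", "b"), c(20, 21))
    y <- rnorm(41)
    group_compare(y, g)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("seeded k-means recovers well-separated subgroups", {
  set.seed(8)
  x <- c(rnorm(5, 0, 0.1), rnorm(12, 5, 0.1), rnorm(3, 10, 0.1))
  lab <- subgroup_kmeans(x)
  expect_equal(as.integer(table(lab)), c(5L, 12L, 3L))
  expect_equal(as.character(lab[1:5]), rep("low", 5))
  expect_equal(as.character(lab[18:20]), rep("high", 3))
  cm <- tapply(x, lab, mean)
  expect_true(cm["low"] < cm["middle"] && cm["middle"] < cm["high"])
  expect_error(subgroup_kmeans(rep(1, 20)), "degenerate")
  expect_error(subgroup_kmeans(rnorm(10)), "at least 18")
})

test_that("median split puts strictly-below-median values in low-error", {
  s21 <- median_split(1:21)
  expect_equal(sum(s21 == "low_error"), 10)
  s4 <- median_split(1:4)
  expect_equal(as.integer(table(s4)), c(2L, 2L))
  # ties at the median go to high-error, by the documented rule
  expect_true(all(median_split(rep(3, 5)) == "high_error"))
})
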