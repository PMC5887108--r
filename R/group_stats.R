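#' One-, two- and paired-sample t tests on cohort measures
#'
#' Thin, guarded wrapper around the standard t statistics used for all
#' group-level magnitude and stability comparisons: one-sample against
#' `mu`, two-sample with pooled variance (Student, df = n1 + n2 - 2;
#' Welch available via `var_equal = FALSE`), and paired. Two-sided p
#' values throughout.
#'
#' @param values numeric outcome vector.
#' @param groups optional factor/character with 2 levels (two-sample),
#'   or `NULL` (one-sample).
#' @param paired_with optional second vector for a paired test.
#' @param mu null value for the one-sample test.
#' @param var_equal pooled-variance (Student) two-sample test?
#' @return list with `t`, `df`, `p`, `estimate`, `method`.
#' @export
group_compare <- function(values, groups = NULL, paired_with = NULL,
                          mu = 0, var_equal = TRUE) {
  if (!is.null(paired_with)) {
    d <- values - paired_with
    if (stats::sd(d) == 0)
      stop("degenerate variance: paired differences are constant")
    ht <- stats::t.test(values, paired_with, paired = TRUE)
    method <- "paired"
  } else if (is.null(groups)) {
    if (stats::sd(values) == 0) stop("degenerate variance: constant values")
    ht <- stats::t.test(values, mu = mu)
    method <- "one-sample"
  } else {
    g <- factor(groups)
    if (nlevels(g) != 2) stop("groups must have exactly 2 levels")
    if (any(tapply(values, g, length) < 2))
      stop("need >= 2 observations per group")
    if (stats::sd(values) == 0) stop("degenerate variance: constant values")
    ht <- stats::t.test(values ~ g, var.equal = var_equal)
    method <- if (var_equal) "two-sample (Student)" else "two-sample (Welch)"
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate), method = method)
}

#' Covariate-adjusted group effect (one-way ANCOVA)
#'
#' F test for the group factor after adjusting for one or more numeric
#' covariates, assuming homogeneous slopes (no interaction term). This
#' equals the squared t of the group coefficient in the linear model
#' `outcome ~ covariates + group`, an equivalence asserted in the test
#' suite.
#'
#' @param outcome numeric outcome.
#' @param group two-level factor.
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
partial_group_effect <- function(outcome, group, covariates) {
  covariates <- as.data.frame(covariates)
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  dat <- data.frame(.y = outcome, .g = g, covariates)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  f_full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(f_full))))
    stop("collinearity among covariates and group")
  f_red <- stats::lm(.y ~ ., data = dat[, setdiff(names(dat), ".g"),
                                        drop = FALSE])
  an <- stats::anova(f_red, f_full)
  Fv <- an$F[2]; pv <- an$`Pr(>F)`[2]
  if (is.na(Fv) && an$RSS[1] < 1e-16) {
    # covariates already explain the outcome perfectly: the group term
    # adds nothing, so its adjusted effect is zero by convention
    Fv <- 0; pv <- 1
  }
  list(F = Fv, df1 = an$Df[2], df2 = an$Res.Df[2], p = pv)
}

#' Multiple linear regression table
#'
#' Ordinary least squares of an outcome on a predictor set, reported in
#' regression-table shape: one row per predictor with the raw-scale
#' coefficient, t statistic, two-sided p value and a significance flag
#' at 0.05. Rows with missing values are dropped listwise.
#'
#' @param outcome numeric outcome.
#' @param predictors data.frame of predictors (columns in the desired
#'   table order; factors allowed).
#' @param standardize z-score numeric predictors before fitting?
#' @return data.frame with `predictor`, `beta`, `t`, `p`, `sig`;
#'   attribute `n` = rows used.
#' @export
regression_table <- function(outcome, predictors, standardize = FALSE) {
  predictors <- as.data.frame(predictors)
  dat <- data.frame(.y = outcome, predictors)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= ncol(predictors) + 1)
    stop("need more observations than predictors")
  if (standardize)
    for (j in names(predictors))
      if (is.numeric(dat[[j]])) dat[[j]] <- as.numeric(scale(dat[[j]]))
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  out <- data.frame(predictor = rownames(sm), beta = sm[, 1],
                    t = sm[, 3], p = sm[, 4],
                    sig = ifelse(sm[, 4] < 0.05, "p < 0.05", "ns"),
                    row.names = NULL)
  attr(out, "n") <- nrow(dat)
  out
}

#' Subgroup magnitudes by seeded 3-cluster k-means
#'
#' Splits scalar grid magnitudes into low/middle/high subgroups by
#' k-means with deterministic centroid seeds: the means of the 6
#' lowest, the 6 middle (central ranks), and the 6 highest magnitudes.
#'
#' @param magnitudes numeric vector, length >= 18.
#' @return factor of labels `low`/`middle`/`high` (cluster means
#'   strictly increasing in that order), with attribute `centers`.
#' @export
subgroup_kmeans <- function(magnitudes) {
  n <- length(magnitudes)
  if (n < 18) stop("need at least 18 magnitudes")
  if (stats::sd(magnitudes) == 0)
    stop("degenerate input: all magnitudes equal")
  s <- sort(magnitudes)
  mid <- ceiling(n / 2)
  seeds <- c(mean(s[1:6]),
             mean(s[(mid - 2):(mid + 3)]),
             mean(s[(n - 5):n]))
  if (any(duplicated(seeds))) stop("degenerate input: duplicated seeds")
  km <- stats::kmeans(matrix(magnitudes, ncol = 1),
                      centers = matrix(seeds, ncol = 1))
  ord <- order(km$centers)
  labels <- c("low", "middle", "high")[match(km$cluster, ord)]
  structure(factor(labels, levels = c("low", "middle", "high")),
            centers = sort(as.numeric(km$centers)))
}

#' Median split into low- and high-error subgroups
#'
#' Values strictly below the sample median form the low-error group;
#' values at or above it the high-error group (for odd n the median is
#' a data point, so with 21 older adults the low-error group has 10
#' members; for even n this matches a plain below/above split; if all
#' values tie at the median, everyone is high-error).
#'
#' @param values numeric vector, length >= 2.
#' @return factor with levels `low_error`, `high_error`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  med <- stats::median(values)
  factor(ifelse(values < med, "low_error", "high_error"),
         levels = c("low_error", "high_error"))
}

#' Group-level statistical surface of a cohort table
#'
#' Reproduces the study's statistical read-out on a cohort table:
#' per-group one-sample tests of the 6-fold magnitude (and any control
#' folds present), young vs old comparisons of magnitude, stability and
#' PI errors, within-group Pearson correlations between magnitude and
#' PI errors, an ANCOVA of the group effect on magnitude controlling
#' for the object-location error distance, and the multiple regression
#' predicting PI performance of older adults from magnitude,
#' demographics and neuropsychological scores.
#'
#' @param tab a [cohort_table()].
#' @return nested list of test results.
#' @export
cohort_stats <- function(tab) {
  young <- tab[tab$group == "young", ]
  old <- tab[tab$group == "old", ]
  res <- list()
  magcols <- grep("^magnitude_[0-9]+fold$", names(tab), value = TRUE)
  res$one_sample <- lapply(stats::setNames(nm = magcols), function(cn)
    list(young = group_compare(young[[cn]]),
         old = group_compare(old[[cn]])))
  res$group <- list(
    magnitude = group_compare(tab$magnitude, tab$group),
    pi_error_body = group_compare(tab$pi_error_body, tab$group),
    pi_error_visual = group_compare(tab$pi_error_visual, tab$group))
  if ("temporal_stability" %in% names(tab))
    res$group$temporal_stability <-
      group_compare(tab$temporal_stability, tab$group)
  cor_of <- function(d, col) {
    if (nrow(d) < 3) return(NULL)
    ct <- stats::cor.test(d$magnitude, d[[col]])
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  res$correlations <- list(
    young = list(body = cor_of(young, "pi_error_body"),
                 visual = cor_of(young, "pi_error_visual")),
    old = list(body = cor_of(old, "pi_error_body"),
               visual = cor_of(old, "pi_error_visual")))
  res$ancova_error_distance <- partial_group_effect(
    tab$magnitude, tab$group, tab$mean_error_distance)
  preds <- c("magnitude", "age", "sex", "sbsod", "corsi",
             "tap_visual_scanning", "tap_working_memory", "dsst", "moca")
  if (sum(stats::complete.cases(old[, preds])) > length(preds) + 1)
    res$regression <- list(
      body = regression_table(old$pi_perf_body, old[, preds]),
      visual = regression_table(old$pi_perf_visual, old[, preds]))
  res$median_split_old <- table(median_split(old$pi_error_body))
  if (nrow(young) >= 18)
    res$subgroups_young <- table(subgroup_kmeans(young$magnitude))
  res
}
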