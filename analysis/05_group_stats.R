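#!/usr/bin/env Rscript
# Stage 5: the full group-level statistical surface.
#
# One-sample tests of the 6-fold magnitude (and 5/7-fold controls) per
# group, young vs old comparisons, within-group magnitude-error
# correlations, the ANCOVA controlling for object-location error
# distance, the multiple regression predicting old-group PI
# performance, the old-group median split and the young-group k-means
# subgrouping.

suppressPackageStartupMessages(library(gridpi))
tab <- read.delim("results/cohort_table.tsv", na.strings = "n/a")
class(tab) <- c("cohort_table", "data.frame")

st <- cohort_stats(tab)
jsonlite::write_json(st, "results/group_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, force = TRUE)

g <- st$group$magnitude
cat(sprintf("magnitude young vs old: t(%d) = %.2f, p = %.4g\n",
            g$df, g$t, g$p))
co <- st$correlations$old$body
cat(sprintf("old group r(magnitude, body-based error) = %.2f, p = %.4g\n",
            co$r, co$p))
cy <- st$correlations$young$body
cat(sprintf("young group r(magnitude, body-based error) = %.2f, p = %.4g\n",
            cy$r, cy$p))
a <- st$ancova_error_distance
cat(sprintf("ANCOVA group effect (error-distance adjusted): F(%d,%d) = %.2f, p = %.4g\n",
            a$df1, a$df2, a$F, a$p))
if (!is.null(st$regression)) {
  cat("\nregression on old-group body-based PI performance:\n")
  print(st$regression$body, digits = 3)
}
cat("\nmedian split of older adults:\n"); print(st$median_split_old)
cat("young k-means subgroups:\n"); print(st$subgroups_young)
cat("wrote results/group_stats.json\n")
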