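#!/usr/bin/env Rscript
# Stage 3: temporal and spatial stability of grid orientations by group.
#
# Temporal stability: proportion of voxels whose orientation changes by
# at most 15 degrees (period 60) between the halves of a run, averaged
# over runs; 0.5 is chance. Spatial stability: Rayleigh z of the voxel
# orientations after mapping the 60-degree domain onto the full circle.

suppressPackageStartupMessages(library(gridpi))
tab <- read.delim("results/cohort_table.tsv", na.strings = "n/a")

out <- aggregate(cbind(temporal_stability, mean_orientation_change,
                       rayleigh_z) ~ group, tab, mean)
write.table(format(out, digits = 6), "results/stability_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(out, digits = 3)

ts_test <- group_compare(tab$temporal_stability, tab$group)
cat(sprintf("\ntemporal stability young vs old: t(%d) = %.2f, p = %.4g\n",
            ts_test$df, ts_test$t, ts_test$p))
old <- tab$temporal_stability[tab$group == "old"]
chance <- group_compare(old, mu = 0.5)
cat(sprintf("old group vs 0.5 chance: t(%d) = %.2f, p = %.4g\n",
            chance$df, chance$t, chance$p))
sp_test <- group_compare(tab$rayleigh_z, tab$group)
cat(sprintf("spatial stability young vs old: t(%d) = %.2f, p = %.4g\n",
            sp_test$df, sp_test$t, sp_test$p))
cat("wrote results/stability_summary.tsv\n")
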