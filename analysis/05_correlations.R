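#!/usr/bin/env Rscript
# Stage 5: cross-system correlations and the cohort summary table.
#
# Pearson correlations (unweighted, one point per system) between
# yield-gap closure and the resource metrics on area and yield-scaled
# bases, plus energy-vs-GWP and EIQ-vs-applications, with two-tailed
# p-values; and area-weighted global and climate-zone aggregates.

suppressMessages(library(ricebench))

metrics <- read_metrics("results/system_metrics.csv")

tab <- results_table(metrics)
utils::write.csv(as.data.frame(tab$correlations),
                 "results/correlations.csv", row.names = FALSE)
utils::write.csv(as.data.frame(tab$global), "results/summary_global.csv",
                 row.names = FALSE)
if (!is.null(tab$by_zone)) {
  utils::write.csv(as.data.frame(tab$by_zone),
                   "results/summary_by_zone.csv", row.names = FALSE)
}

sig <- tab$correlations[tab$correlations$p_value < 0.01, ]
message(sprintf("significant correlations (p < 0.01, n = %d systems):",
                unique(tab$correlations$n)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %s vs %s: r = %+.2f", sig$metric_x[i],
                  sig$metric_y[i], sig$r[i]))
}
message("wrote results/correlations.csv, results/summary_global.csv",
        if (!is.null(tab$by_zone)) ", results/summary_by_zone.csv" else "")
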