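#!/usr/bin/env Rscript
# Stage 3: six-dimension performance scores and the overall index.
#
# Each system is scored on yield gap, yield-scaled GWP, water supply,
# pesticide applications, N-balance deviation from the 8 kg N/Mg target,
# and yield-scaled labor, normalized to the cohort maximum (lower is
# better). The overall index averages three blocks — yield gap, the four
# resource scores, labor — so each pillar carries similar weight.

suppressMessages(library(ricebench))

cfg <- default_config()
metrics <- read_metrics("results/system_metrics.csv")

scores <- normalize_scores(metrics, cfg)
radar_export(scores, "results/radar_scores.csv")
utils::write.csv(as.data.frame(scores), "results/performance_index.csv",
                 row.names = FALSE)

ord <- scores[order(scores$overall_index), ]
message("overall performance index (lower = better):")
message(sprintf("  best : %s", paste(sprintf("%s (%.2f)",
  head(ord$system_code, 3), head(ord$overall_index, 3)), collapse = ", ")))
message(sprintf("  worst: %s", paste(sprintf("%s (%.2f)",
  tail(ord$system_code, 3), tail(ord$overall_index, 3)), collapse = ", ")))
by_zone <- tapply(scores$overall_index, scores$group, mean)
message(sprintf("  zone means: %s", paste(sprintf("%s %.2f",
  names(by_zone), by_zone), collapse = ", ")))
message("wrote results/radar_scores.csv, results/performance_index.csv")
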