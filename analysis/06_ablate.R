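#!/usr/bin/env Rscript
# Stage 6 — ablation: re-runs selection + LOPO for ten feature-set
# configurations (all four wearable/weather groups, minus each, only each,
# none), with daily-routine features always included, and tests each
# configuration against routine-only via paired Wilcoxon over perturbations.
# Writes ablation.csv.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
abl <- run_pipeline(cfg, "ablate", ART_DIR, group = "ms2",
                    candidates = analysis_candidates("ms2"))

cat("\n")
print(as.data.frame(abl)[, c("configuration", "n_selected", "r2_complete",
                             "p_vs_routine")], row.names = FALSE)
best <- abl$configuration[which.max(abl$r2_complete)]
cat(sprintf("\nBest configuration for the dysfunctional-ANS group: %s\n", best))
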