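#!/usr/bin/env Rscript
# Stage 2 — feature extraction: estimates nightly sleep from acceleration and
# heart rate, builds the five aggregation horizons per rating (1 h / 3 h /
# 6 h / asleep / awake), computes rest-window Poincare HRV, heart-rate, EDA
# (levels and peak counts), skin-temperature, activity, routine and weather
# features, and writes features.csv with per-feature missingness masks.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
ft <- run_pipeline(cfg, "extract", ART_DIR)

m <- as.matrix(as.data.frame(ft)[paste0("miss_", feature_names(ft))])
cat(sprintf("\nExtracted %d feature vectors x %d features.\n",
            nrow(ft), length(feature_names(ft))))
cat(sprintf("%.1f%% of vectors are incomplete; most-missing feature: %s\n",
            100 * mean(rowSums(m) > 0),
            sub("^miss_", "", names(which.max(colSums(m))))))
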