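#!/usr/bin/env Rscript
# Stage 1 — simulate the cohort: raw wearable streams (heart rate, EDA, skin
# temperature, acceleration, inter-beat intervals, steps), sleep schedules,
# daily weather and VAS fatigue ratings produced by a known additive ground
# truth over the extracted features. Writes per-channel CSVs, ratings,
# participants, weather, truth.json and a manifest under results/pipeline/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
spec <- analysis_spec()
cohort <- run_pipeline(cfg, "simulate", ART_DIR, spec = spec)

cat(sprintf("\nSimulated %d participants (%s), %d ratings over %d days.\n",
            nrow(cohort$participants),
            paste(names(table(cohort$participants$group)),
                  table(cohort$participants$group), collapse = ", "),
            nrow(cohort$ratings), spec$days))
cat(sprintf("Mean VAS %.2f (participant means %.1f-%.1f); artifacts on disk in %s\n",
            mean(cohort$ratings$vas),
            min(cohort$participants$vas_mean), max(cohort$participants$vas_mean),
            ART_DIR))
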