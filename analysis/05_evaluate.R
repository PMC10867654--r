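#!/usr/bin/env Rscript
# Stage 5 — evaluation: within-group leave-one-participant-out for each
# group, across-group transfer of the control model onto the
# dysfunctional-ANS group, the participant-mean baseline (R2 = 0 by
# construction), and paired Wilcoxon tests. Appends rows to evaluation.csv.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
run_pipeline(cfg, "evaluate", ART_DIR, train = "co", test = "co")
run_pipeline(cfg, "evaluate", ART_DIR, train = "ms2", test = "ms2")
run_pipeline(cfg, "evaluate", ART_DIR, train = "co", test = "ms2")

ev <- read.csv(file.path(ART_DIR, "evaluation.csv"))
cat("\n")
print(ev[, c("train", "test", "n_participants", "r2_complete", "r2_imputed",
             "r2_baseline", "p_vs_baseline")], row.names = FALSE)
drop <- ev$r2_complete[ev$train == "co" & ev$test == "co"] -
  ev$r2_complete[ev$train == "co" & ev$test == "ms2"]
cat(sprintf("\nTransferring the control model onto the dysfunctional-ANS group costs %.1f R2 points.\n",
            drop))
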