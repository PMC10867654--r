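#!/usr/bin/env Rscript
# Stage 4 — variable selection per participant group: fits the shrinkage
# additive model on subsamples (each excluding two participants), averages
# per-term EDF and p-values, purges terms with mean EDF < 0.1, then removes
# the worst term while any mean p exceeds 0.05; finally refits on all
# participants and re-applies both rules. Writes model_<group>.json.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
for (g in c("co", "ms2")) {
  cand <- analysis_candidates(g)
  sel <- run_pipeline(cfg, "fit", ART_DIR, group = g, candidates = cand)
  cat(sprintf("\nGroup %s: %d of %d candidates kept: %s\n", g,
              length(sel$selected), length(cand),
              paste(sel$selected, collapse = ", ")))
}
cat("\nSelection traces are stored in model_co.json / model_ms2.json\n")
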