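# Shared configuration for the analysis drivers. Desk-scale cohort: two
# groups with disjoint ground-truth effect sets (healthy controls and
# dysfunctional-ANS patients), one week of recordings.

library(fatiguecast)

ART_DIR <- "results/pipeline"

analysis_config <- function() {
  run_config(seed = 2024, k = 8, n_subsamples = 25, n_perturbations = 12)
}

analysis_spec <- function() {
  cohort_spec(n_co = 7, n_ms1 = 0, n_ms2 = 7, days = 10,
              missing_rate = 0.25, noise_sd = 0.8, seed = 2024)
}

# Candidate set per group: the group's ground-truth features plus decoys
# covering every feature group. Kept moderate so each subsample (two
# participants excluded) retains >= 10 rows per candidate term.
analysis_candidates <- function(group) {
  truth <- default_truth_model()
  g <- c(co = "CO", ms2 = "MS_II")[[group]]
  union(truth$effects[[g]]$feature,
        c("hr_3h_mean", "eda_1h_mean", "acc_1h_max", "steps_6h_count"))
}
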