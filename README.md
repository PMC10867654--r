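# fatiguecast

Momentary (state) fatigue — a 1–10 visual-analog-scale self-report collected
several times a day — varies with time of day, sleep, autonomic state and
behavior. `fatiguecast` is an R package plus analysis workflow for modeling
that variation from arm-worn wearable biosignals in multiple sclerosis
patients and healthy controls: heart rate, inter-beat intervals,
electrodermal activity, skin temperature, acceleration and steps, plus daily
weather. It is aimed at researchers in digital biomarkers and ecological
momentary assessment who need a tested, fully reproducible reference pipeline
— including a synthetic cohort generator with known ground truth, since the
clinical recordings the design mirrors are not publicly deposited.

## The model

Per participant group (controls `CO`; MS patients with functional /
dysfunctional autonomic nervous system, `MS I` / `MS II` by abbreviated
COMPASS score > 17), normalized ratings follow a Gaussian additive model

    y = α + Σ_j f_j(x_j) + ε,

where each `f_j` is a penalized regression spline with a shrinkage penalty on
its null space, so irrelevant effects vanish (EDF → 0). Variables are chosen
by subsample backward elimination: fit on `n_subsamples` subsamples, each
excluding all rows of two random participants; average per-term EDF and
p-values; purge all terms with mean EDF < 0.1, then repeatedly remove the
worst term while any mean p > 0.05; refit on everyone and re-apply the rules.
Features are aggregated over five horizons anchored at each rating (1 h, 3 h,
6 h — clipped at wake — the prior sleep period, and since waking), with
heart-rate variability (SDNN, SD1, SD2 from the Poincaré plot; SD1 ≡
RMSSD/√2) computed only in 5-minute low-motion rest windows where mean HR <
0.55 × (220 − age) and fewer than 4 inter-beat intervals are artifacts.
Evaluation is leave-one-participant-out within groups and transfer across
groups, against a participant-mean baseline whose R² is exactly 0 by
construction, with paired Wilcoxon signed-rank comparisons and a
feature-group ablation study (cardiac / electrodermal / activity / weather;
routine features always included).

## Worked example

Generate a small two-group cohort with known ground truth, push it through
the whole pipeline, and compare the selected model against the truth:

```r
library(fatiguecast)

cfg  <- run_config(seed = 5, k = 8, n_subsamples = 40)
spec <- cohort_spec(n_co = 10, n_ms1 = 0, n_ms2 = 0, days = 14, seed = 5)
co   <- generate_cohort(spec, config = cfg)

# re-extract features from the raw streams (sleep estimated from the data)
tabs <- lapply(names(co$bundles), function(pid) {
  b <- co$bundles[[pid]]
  r <- co$ratings[co$ratings$participant_id == pid, c("rating_id", "time", "vas")]
  assemble_features(b, r, estimate_sleep_wake(b$acc, b$hr), co$weather, cfg)
})
```

followed by `normalize_per_participant()`, `impute_zero()`, then
`backward_eliminate()` over the group's true effects plus eight decoy
features, and `lopo_evaluate()`. On this seed the run prints:

```
truth:    time_of_day sdnn_6h_mean sd1_3h_min steps_6h_count dew_day_mean
selected: dew_day_mean sd1_3h_min sdnn_6h_mean steps_6h_count time_of_day
eval group -> group: n=10 participants, R2 27.0% (complete), 27.4% (imputed)
baseline r2: 0
```

All five ground-truth effects are recovered, no decoy survives, and the
within-group leave-one-participant-out model explains 27% of the normalized
rating variance where the participant-mean baseline explains exactly 0% —
the regime the design targets for a well-behaved group.

The step-by-step workflow lives in `analysis/01_simulate.R` …
`analysis/06_ablate.R`: thin drivers over `run_pipeline()` that write plain
CSV artifacts and JSON manifests under `results/pipeline/` and narrate what
each stage found.

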