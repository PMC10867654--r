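---
title: "Modeling momentary fatigue from wearable biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling momentary fatigue from wearable biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Perceived (state) fatigue — a 1–10 visual-analog-scale (VAS) self-report —
varies within a day, and in multiple sclerosis it is the most common and most
disabling symptom. `fatiguecast` implements a pipeline that asks how much of
that within-day variation can be explained by passively collected wearable
biosignals: heart rate, inter-beat intervals (IBIs), electrodermal activity
(EDA), skin temperature, acceleration and step counts from an arm-worn
sensor, plus daily weather. Three participant groups are modeled separately:
healthy controls (CO), MS patients with a functional autonomic nervous
system (MS I, abbreviated COMPASS score ≤ 17) and MS patients with a
dysfunctional one (MS II, COMPASS > 17).

Because the clinical recordings the design is based on are not publicly
deposited, the package ships a first-class synthetic cohort generator with a
known ground truth. Every downstream claim the package makes is tested
against that truth.

## The model

For each group, normalized VAS ratings are modeled as a Gaussian additive
model over per-rating features \(x_1, \dots, x_p\):

\[ y = \alpha + \textstyle\sum_j f_j(x_j) + \varepsilon, \]

with every \(f_j\) a penalized regression spline that carries a shrinkage
penalty on its null space, so a term with no explanatory power is shrunk to
*exactly* nothing (its effective degrees of freedom, EDF, go to 0). Penalty
weights are chosen by numerical GCV optimization (`method = "REML"` is
available; GCV is the default and markedly faster, though it undersmooths
pure-noise terms in a minority of single fits — the selection loop below
absorbs this by averaging over subsamples). The default basis is mgcv's
shrinkage cubic regression spline (`bs = "cs"`, `k = 10`); the shrinkage
thin-plate basis and the explicit double-penalty construction
(`bs = "tp"` + `select = TRUE`) are one `run_config()` switch away and give
equivalent 1-D fits at several times the cost, which matters when the
selection loop multiplies fit time by thousands.

### Variable selection

`backward_eliminate()` runs the subsample backward elimination:

1. Fit the model on `n_subsamples` subsamples (default 1000; the test suite
   uses 25–50), each excluding **all rows of two randomly drawn
   participants**; average each term's EDF and p-value across subsamples.
2. Purge *all* terms with mean EDF < 0.1 (shrunk away on most subsamples).
3. Otherwise, while any mean p-value exceeds 0.05, remove the single worst
   term (ties broken by removing the lexicographically last name —
   deterministic).
4. On convergence, refit on all participants and re-apply both rules until
   stable.

The procedure is deterministic under a seed, and the returned
`elimination_trace` records every iteration's candidate set, mean EDF/p and
action.

## Features and the five horizons

Each rating gets features aggregated over five windows anchored at the
rating: 1 h, 3 h and 6 h look-backs (clipped at the last wake time, so they
never reach into sleep — a rating under one hour after waking makes the 1 h,
3 h, 6 h and since-waking windows identical), the prior completed sleep
interval, and the since-waking window.

* **Cardiac (CAR)**: HR min/max/mean/SD/slope from 1-minute means; SDNN, SD1,
  SD2 aggregated over 5-minute rest windows (below), with slopes fitted over
  per-window values. Skin-temperature aggregates are also emitted and tagged
  CAR — the four-group ablation taxonomy has no thermal slot and
  thermoregulation is autonomically driven; they never enter default truth
  models.
* **EDA**: level aggregates plus peak counts — a peak is a local maximum of
  the baseline-subtracted signal (centred 5-minute moving average) with
  height ≥ 0.05 signal units; the "variability of peaks" feature is the
  population SD of per-5-minute-subwindow counts. At the default one-sample-
  per-minute test scale a literal 0.05 Hz high-pass sits above Nyquist, so
  baseline subtraction stands in for it; both window and threshold are
  configurable.
* **Activity (ACC)**: acceleration aggregates, its trapezoidal integral
  (acceleration·hours, constant-extended to the window edges), and step
  counts with edge intervals prorated by overlap.
* **Routine**: time of day, time awake, prior sleep duration, and deviations
  of that night's bed/wake clock time from the participant's study mean.
* **Weather (WEA)**: day-level temperature (mean/min), felt minimum
  temperature, dew and humidity, constant across a day's ratings.

### Rest windows and HRV

HRV is only trusted where an arm-worn optical sensor can measure it: 5-minute
windows on a global grid in which (i) mean HR < 0.55 × (220 − age), (ii) the
acceleration magnitude shows no measurable continuous motion — population SD
below `motion_sd_threshold` (default 0.05 generator units; the underlying
protocol states no number), and (iii) fewer than 4 IBIs are artifacts, which
are linearly interpolated. An artifact is an IBI deviating more than 25% from
the median of the five preceding accepted IBIs (a Malik-style rule; the
reference implementation is not public, so the rule and its 25% are
configurable). Anchoring windows on a global 5-minute grid (rather than
per-horizon) keeps windows non-overlapping, tiled, and computable once per
participant instead of once per rating × horizon.

SDNN is the population SD of the window's IBIs; SD1 is the RMS perpendicular
distance of consecutive-IBI pairs to the Poincaré identity line, which makes
SD1 = RMSSD/√2 an exact identity (a mean-centred SD1 would violate it in the
15th decimal whenever the mean successive difference is non-zero); SD2 is the
population SD of the along-line coordinate. `audit_rest_windows()` is an
independent brute-force re-checker used by the tests: no emitted window may
violate any gating rule.

### Sleep and wake

`estimate_sleep_wake()` is a deliberately simple actigraphy-style heuristic
(the underlying protocol does not specify its algorithm): 1-minute epochs are
quiet when smoothed acceleration and smoothed HR fall below quantile-anchored
cuts; the longest quiet run per night (noon-to-noon) of at least 3 h becomes
the main sleep period, snapped to minutes. On generator data it recovers
true onsets/wakes to a few minutes; on real data it is a stand-in and the
single most uncertain component of the pipeline.

## Normalization, imputation, baseline

Features and ratings are normalized per participant — subtract the
participant's mean, divide by the participant's population SD, computed over
the full study ignoring missing values (the population/n convention makes toy
examples exact; sample-SD users can rescale). Missing values are then imputed
with zero, which *is* the participant mean on that scale. Models are selected
and trained on rows without any imputed cell and evaluated both ways.

Two consequences worth knowing:

* The baseline regressor (predict each participant's own mean, i.e. 0)
  has exactly zero explained variance under the evaluation definition
  `R² = 1 − Σ(y−ŷ)²/Σy²` (total sum of squares about 0). That zero is an
  algebraic identity, not an empirical result, and it pins down the R²
  definition: no other convention makes the baseline exactly 0 for every
  participant.
* Normalization stats are computed once per participant over the whole study,
  not per cross-validation fold — mirroring the modeled protocol. This leaks
  a small amount of held-out information into training; we keep it for
  fidelity and note it as a limitation.

## Evaluation protocols

* **Within-group**: leave-one-participant-out; train on the remaining
  participants' complete cases, evaluate on the held-out participant twice —
  complete cases only, and all rows with imputation. Group metrics are
  unweighted means over participants.
* **Across-group**: one model on all of the training group's complete cases
  (using the *training* group's selected variables), evaluated per
  participant of a disjoint test group; paired Wilcoxon signed-rank tests
  compare across-group with within-group per-participant R². The exact
  signed-rank distribution is computed by convolution (mid-ranks doubled to
  integers) for n ≤ 25 because ties — ubiquitous in paired R² values — make
  `stats::wilcox.test`'s exact path unavailable; larger n uses the normal
  approximation with continuity correction.
* **Ablation**: ten configurations over the CAR/EDA/ACC/WEA groups (all,
  minus each, only each, none), routine features always included; each runs
  the full selection + LOPO. Significance against routine-only uses paired
  Wilcoxon over `n_perturbations` perturbations. "Perturbation" is not
  precisely defined in the modeled protocol; here each perturbation excludes
  two random participants, refits on the remainder's complete cases and
  scores the excluded pair out of sample, with exclusion draws shared across
  configurations for pairing.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: three groups (defaults
23/27/24 participants), 14 rating days, ~3.8 ratings per day (Poisson,
uniform over waking hours — the within-day rating-time distribution is a
modeling choice, not a reported fact), and ~25% incomplete feature vectors.
Generation is two-stage: raw streams are synthesized first, features are
extracted from them with the *same* extractor the pipeline uses, and ratings
are then produced by a known additive truth model on the normalized
features — so extractor/generator mismatch can never masquerade as model
error. The truth record (tabulated effect curves, shape labels, noise SD) is
retained for recovery tests.

Channel models are intentionally minimal: sleep onset ~ 23:00 ± 1 h and
duration ~ 8 ± 1 h per night; activity as a low rest baseline plus bounded
bouts (~1.8/h, 5–15 min); HR as a wake baseline (~74 bpm) plus an activity
response, dropping ~18 bpm in sleep with per-night offsets; skin temperature
as a slow sinusoid; EDA as a tonic drift plus Poisson-timed
exponential-decay SCR bumps with hourly rate modulation; IBIs as an AR(1)
around 60000/HR with wake/sleep marginal SDs (~45/62 ms) and lag-1
correlation 0.55, plus ~0.12% multiplicative artifacts. The default ground
truth gives each group 5–6 bounded effects (tanh-shaped monotone, plus one
concave option) with amplitudes 0.25–0.55 on the normalized-latent scale, a
0.03/h time-of-day trend, and rating noise SD 0.8 — producing within-group
explained variances in the high-20s/low-30s percent range, the regime the
design targets. VAS = clip(participant mean + participant SD × latent, 1,
10), rounded to 0.1.

Missingness is injected *into the streams*, not the table: motion bursts are
pasted into the hour before a random subset of ratings (clipped at wake), so
rest windows fail and 1-hour cardiac features go missing — reproducing the
dominant real-world missingness mode. The realized incomplete fraction
tracks `missing_rate` to within a few points; essentially every incomplete
vector is missing a cardiac feature.

What the generator does **not** emulate: circadian HRV structure, sleep
stages, device synchronization dropouts, EDA storms, medication effects, or
any pathology beyond group-specific effect sets and rating levels. Passing
recovery tests therefore demonstrates that the pipeline is correct and
sensitive under its own assumptions — not that those effects exist in real
patients.

## Numerical and design choices

* Population (÷n) SDs everywhere; OLS slopes in units/hour; half-open
  `[start, end)` window membership.
* Basis dimension `k = 10` default (tests use 8 — at a few hundred rows per
  group the extra flexibility is pure variance); GCV default; 1e-9-scale
  tolerances only where algebraic identities are asserted.
* Elimination tie-break: lexicographically last name. Subsample count
  defaults to 1000 but is a mean and stable at a few dozen; the modeled
  protocol itself reports both "1000 sub-samples" and "100 splits", so the
  count is configurable rather than fixed.
* Degenerate inputs: zero-variance participant-columns are masked with a
  warning (never divided by zero); horizons without data yield missing
  features, never errors; empty rest-window sets are valid results; an empty
  candidate list returns an empty selection with a trace.
* Timestamps are local ISO-8601 with explicit UTC offset (fixed +01:00 zone)
  because fatigue is diurnal in local time; all internal arithmetic is in
  seconds from the participant's first local midnight.
* Test-scale problem sizes, chosen once: unit fixtures use 4–10 participants
  × 4–14 days at one sample/minute; the selection operating-characteristic
  study uses 30 participants × 25 ratings × 50 subsamples × 20 seeds; the
  end-to-end recovery cohort uses 10 controls + 10 dysfunctional-ANS
  patients × 14 days with 25 subsamples; the analysis drivers use 7 + 7
  participants × 10 days. Package defaults remain at protocol scale
  (1000 subsamples, 100 perturbations).

## Recorded inconsistencies and open questions

The modeled protocol reports 3733 data points with 927 incomplete, yet also
"2234 data points" without imputed values (3733 − 927 = 2806); the
complete-case operation here simply returns rows minus incomplete rows and
the discrepancy is recorded, not resolved. The mean-VAS~FSMC Spearman
correlation is quoted as 0.78 in one place and 0.79 in another. Whether
selection ran on complete cases only is not explicit; complete-case is used
here, consistent with models being "trained omitting any data points with
imputed data".

## Interfaces

The analysis drivers under `analysis/` (01_simulate → 06_ablate) are the
command-line surface: each is a thin `Rscript` over `run_pipeline()`, which
writes plain CSV artifacts plus JSON manifests (seed, config hash, counts)
and enforces stage dependencies. A standalone YAML-driven CLI binary was
deliberately not built — for an analysis package the scripts, functions and
this document are the interface.
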