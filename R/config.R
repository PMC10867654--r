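#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the study protocol the pipeline models: heart-rate
#' variability is only computed in 5-minute low-motion rest windows where the
#' mean heart rate stays below `rest_hr_fraction * (220 - age)` bpm, smooth
#' terms are eliminated when their mean effective degrees of freedom across
#' subsamples fall below `edf_threshold` or their mean p-value exceeds
#' `p_threshold`, and features are aggregated over 1, 3 and 6 hour horizons
#' plus the prior-sleep and since-waking windows.
#'
#' @param seed integer seed recorded in every stage manifest.
#' @param sampling_rate sampling rate in Hz for the uniformly sampled channels
#'   (heart rate, electrodermal activity, skin temperature, acceleration).
#'   The default of one sample per minute keeps simulated cohorts small; the
#'   device-native 1 Hz is supported.
#' @param n_subsamples number of subsamples per elimination iteration, each
#'   excluding two participants.
#' @param edf_threshold mean-EDF purge threshold of the elimination loop.
#' @param p_threshold mean p-value removal threshold of the elimination loop.
#' @param rest_hr_fraction fraction of age-predicted maximum heart rate below
#'   which a participant counts as at rest.
#' @param horizon_hours lengths (hours) of the fixed look-back horizons.
#' @param motion_sd_threshold maximum population SD of the acceleration
#'   magnitude inside a 5-minute window for it to count as motion free.
#' @param max_artifact_ibis windows with at least this many artifact
#'   inter-beat intervals are rejected; fewer are linearly interpolated.
#' @param min_ibis_per_window minimum beats for a valid rest window.
#' @param artifact_rel_dev relative deviation from the running median of the
#'   five preceding accepted inter-beat intervals that flags an artifact.
#' @param eda_baseline_window width (seconds) of the centred moving-average
#'   baseline subtracted from the electrodermal signal before peak detection.
#' @param eda_prominence minimum prominence of an electrodermal peak, in the
#'   (arbitrary) units of the signal.
#' @param k basis dimension of each smooth term.
#' @param method smoothness-selection criterion passed to `mgcv::gam`
#'   (`"GCV.Cp"` default, `"REML"` available; REML shrinks null effects more
#'   aggressively at small n, GCV is markedly faster).
#' @param basis smooth basis: `"cs"` (shrinkage cubic regression spline,
#'   default — low-rank, knot-based, shrinks the null space so terms can
#'   vanish) or `"ts"` (shrinkage thin-plate); `"tp"`/`"cr"` select the
#'   unshrunk bases and add the explicit double penalty
#'   (`mgcv::gam(select = TRUE)`) instead.
#' @param n_perturbations perturbations used for ablation significance tests.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sampling_rate = 1 / 60,
                       n_subsamples = 1000L,
                       edf_threshold = 0.1,
                       p_threshold = 0.05,
                       rest_hr_fraction = 0.55,
                       horizon_hours = c(1, 3, 6),
                       motion_sd_threshold = 0.05,
                       max_artifact_ibis = 4L,
                       min_ibis_per_window = 10L,
                       artifact_rel_dev = 0.25,
                       eda_baseline_window = 300,
                       eda_prominence = 0.05,
                       k = 10L,
                       basis = "cs",
                       method = "GCV.Cp",
                       n_perturbations = 100L) {
  cfg <- list(
    seed = as.integer(seed),
    sampling_rate = sampling_rate,
    n_subsamples = as.integer(n_subsamples),
    edf_threshold = edf_threshold,
    p_threshold = p_threshold,
    rest_hr_fraction = rest_hr_fraction,
    horizon_hours = sort(horizon_hours),
    motion_sd_threshold = motion_sd_threshold,
    max_artifact_ibis = as.integer(max_artifact_ibis),
    min_ibis_per_window = as.integer(min_ibis_per_window),
    artifact_rel_dev = artifact_rel_dev,
    eda_baseline_window = eda_baseline_window,
    eda_prominence = eda_prominence,
    k = as.integer(k),
    basis = match.arg(basis, c("cs", "ts", "tp", "cr")),
    method = match.arg(method, c("GCV.Cp", "REML")),
    n_perturbations = as.integer(n_perturbations)
  )
  num_pos <- c("sampling_rate", "edf_threshold", "rest_hr_fraction",
               "motion_sd_threshold", "artifact_rel_dev",
               "eda_baseline_window", "eda_prominence")
  for (nm in num_pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stopf("config field '%s' must be a single strictly positive number", nm)
    }
  }
  if (cfg$p_threshold <= 0 || cfg$p_threshold >= 1) {
    stopf("p_threshold must lie in (0, 1)")
  }
  if (any(cfg$horizon_hours <= 0)) stopf("horizon_hours must be positive")
  if (cfg$n_subsamples < 1L || cfg$n_perturbations < 1L) {
    stopf("subsample and perturbation counts must be at least 1")
  }
  if (cfg$k < 3L) stopf("basis dimension k must be at least 3")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("fatiguecast run configuration\n")
  cat(sprintf("  seed %d | sampling %.4g Hz | k=%d | subsamples %d\n",
              x$seed, x$sampling_rate, x$k, x$n_subsamples))
  cat(sprintf("  rest HR < %.2f x (220-age); motion SD < %.3g; EDF>=%.2g; p<=%.2g\n",
              x$rest_hr_fraction, x$motion_sd_threshold,
              x$edf_threshold, x$p_threshold))
  invisible(x)
}

#' Participant metadata record
#'
#' @param id participant identifier.
#' @param group one of `"CO"`, `"MS_I"`, `"MS_II"`. Patients with an
#'   abbreviated COMPASS autonomic-symptom score above 17 are classed as
#'   having a dysfunctional autonomic nervous system (`MS_II`), the rest of
#'   the patients as `MS_I`; controls are `CO`.
#' @param age age in years, 18-65.
#' @param sex `"f"` or `"m"`.
#' @param compass abbreviated COMPASS score (>= 0).
#' @param fsmc Fatigue Scale for Motor and Cognitive Functions total score,
#'   or `NA` if the questionnaire was not completed.
#' @return one-row `data.frame`.
#' @export
participant <- function(id, group, age, sex = "f", compass = 0, fsmc = NA_real_) {
  group <- match.arg(group, c("CO", "MS_I", "MS_II"))
  if (age < 18 || age > 65) stopf("age must be in [18, 65]")
  if (compass < 0) stopf("compass score must be >= 0")
  if (group == "MS_II" && compass <= 17) {
    stopf("MS_II requires a COMPASS score above 17")
  }
  if (group == "MS_I" && compass > 17) {
    stopf("MS_I requires a COMPASS score of 17 or below")
  }
  data.frame(id = as.character(id), group = group, age = age,
             sex = sex, compass = compass, fsmc = fsmc,
             stringsAsFactors = FALSE)
}
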