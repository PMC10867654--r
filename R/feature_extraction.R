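# Feature extraction: raw wearable streams -> per-rating feature vectors over
# the five aggregation horizons (1 h, 3 h, 6 h before the rating, the prior
# sleep period, and since waking).

.HORIZON_KEYS <- c("1h", "3h", "6h", "aw", "as")
.WIN <- 300  # rest-window width, seconds (5 min)

#' Enumerate the feature census
#'
#' All features the extractor emits, with their feature-group tag:
#' cardiac/autonomic (CAR: heart rate, SDNN, SD1, SD2, skin temperature),
#' electrodermal (EDA), physical activity (ACC: acceleration and steps),
#' weather (WEA) and daily routine (ROUTINE). Non-routine names encode
#' `(signal, horizon, statistic)`, e.g. `sdnn_3h_min`.
#'
#' @return data.frame with columns `name`, `group`.
#' @export
feature_census <- function() {
  stats5 <- c("min", "max", "mean", "sd", "slope")
  grid <- function(sig, stats) {
    as.vector(t(outer(.HORIZON_KEYS, stats,
                      function(h, s) paste(sig, h, s, sep = "_"))))
  }
  out <- rbind(
    data.frame(name = grid("hr", stats5), group = "CAR"),
    data.frame(name = grid("sdnn", stats5), group = "CAR"),
    data.frame(name = grid("sd1", stats5), group = "CAR"),
    data.frame(name = grid("sd2", stats5), group = "CAR"),
    data.frame(name = grid("temp", stats5), group = "CAR"),
    data.frame(name = grid("eda", stats5), group = "EDA"),
    data.frame(name = grid("eda_peaks", c("count", "sd")), group = "EDA"),
    data.frame(name = grid("acc", c("mean", "min", "max", "sd", "int")), group = "ACC"),
    data.frame(name = grid("steps", "count"), group = "ACC"),
    data.frame(name = c("time_of_day", "time_awake", "sleep_duration",
                        "wake_dev", "bed_dev"), group = "ROUTINE"),
    data.frame(name = c("temp_day_mean", "temp_day_min", "felttemp_day_min",
                        "dew_day_mean", "humidity_day_mean"), group = "WEA")
  )
  rownames(out) <- NULL
  out
}

#' Map feature names to their feature group
#'
#' @param names character vector of feature names.
#' @return named character vector of groups.
#' @export
feature_groups <- function(names) {
  census <- feature_census()
  g <- census$group[match(names, census$name)]
  names(g) <- names
  g
}

# ---- sleep/wake -------------------------------------------------------------

# 1-minute epoch means of a (time, value) series.
minute_means <- function(df) {
  if (nrow(df) == 0L) return(data.frame(time = numeric(0), value = numeric(0)))
  ep <- floor(df$time / .MIN)
  v <- tapply(df$value, ep, mean)
  out <- data.frame(time = as.numeric(names(v)) * .MIN + .MIN / 2,
                    value = as.numeric(v))
  out[order(out$time), , drop = FALSE]
}

# centred running mean; ends fall back to the raw values
runmean <- function(x, w) {
  if (length(x) < w || w < 2L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Estimate nightly sleep intervals from acceleration and heart rate
#'
#' Heuristic actigraphy-style detector: 1-minute epochs are scored as quiet
#' when both the smoothed acceleration magnitude and the smoothed heart rate
#' fall below data-driven cuts; per night (noon to noon) the longest quiet
#' run of at least `min_sleep_h` hours becomes the main sleep period.
#' Onset/wake are snapped to 1-minute resolution.
#'
#' @param acc,hr data.frames with columns `time` (s), `value`.
#' @param min_sleep_h shortest admissible main sleep period, hours.
#' @return data.frame of class `sleep_schedule` with columns `night`,
#'   `onset`, `wake` (seconds). Nights without a detected sleep period are
#'   absent from the table.
#' @export
estimate_sleep_wake <- function(acc, hr, min_sleep_h = 3) {
  span <- max(acc$time, hr$time) - min(acc$time, hr$time)
  if (span < .DAY) stopf("insufficient data: need at least 24 h, got %.1f h", span / .HOUR)
  am <- minute_means(acc)
  hm <- minute_means(hr)
  ep <- merge(am, hm, by = "time", suffixes = c("_acc", "_hr"))
  ep <- ep[order(ep$time), ]
  ep$sacc <- runmean(ep$value_acc, 9)
  ep$shr <- runmean(ep$value_hr, 9)
  qa <- stats::quantile(ep$sacc, c(0.05, 0.95), names = FALSE)
  qh <- stats::quantile(ep$shr, c(0.05, 0.95), names = FALSE)
  acc_cut <- qa[1] + 0.20 * (qa[2] - qa[1])
  hr_cut <- qh[1] + 0.35 * (qh[2] - qh[1])
  quiet <- ep$sacc <= acc_cut & ep$shr <= hr_cut
  # nights run noon -> noon so a ~23:00 onset sits mid-window
  night <- floor((ep$time - 12 * .HOUR) / .DAY)
  out <- list()
  for (ng in sort(unique(night))) {
    idx <- which(night == ng)
    q <- quiet[idx]
    r <- rle(q)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    if (r$lengths[best] * .MIN < min_sleep_h * .HOUR) next
    onset <- ep$time[idx[starts[best]]] - .MIN / 2
    wake <- ep$time[idx[ends[best]]] + .MIN / 2
    out[[length(out) + 1L]] <- data.frame(
      night = ng, onset = round(onset / .MIN) * .MIN,
      wake = round(wake / .MIN) * .MIN)
  }
  sched <- if (length(out)) do.call(rbind, out) else
    data.frame(night = integer(0), onset = numeric(0), wake = numeric(0))
  class(sched) <- c("sleep_schedule", "data.frame")
  sched
}

#' Build the five aggregation horizons for one rating
#'
#' The 1/3/6-hour windows end at the rating and are clipped at the most
#' recent wake time, so they never reach into sleep: a rating less than one
#' hour after waking makes the 1 h, 3 h, 6 h and since-waking windows
#' identical; between one and three hours after waking the 3 h, 6 h and
#' since-waking windows coincide. The asleep window is the most recent
#' completed sleep interval.
#'
#' @param rating_time rating time, seconds.
#' @param schedule a [estimate_sleep_wake()] schedule.
#' @param horizon_hours fixed horizon lengths in hours (default 1, 3, 6).
#' @return list with elements `h1`, `h3`, `h6`, `aw` (each `c(start, end)`),
#'   `as` (`c(onset, wake)` or `NULL` if no completed sleep precedes the
#'   rating), plus `wake` and `onset`.
#' @export
build_horizons <- function(rating_time, schedule, horizon_hours = c(1, 3, 6)) {
  done <- schedule[schedule$wake <= rating_time, , drop = FALSE]
  if (nrow(done) == 0L) {
    stopf("rating at %.0f s precedes the first detected wake", rating_time)
  }
  last <- done[which.max(done$wake), ]
  wake <- last$wake
  hz <- lapply(horizon_hours, function(h) {
    c(max(rating_time - h * .HOUR, wake), rating_time)
  })
  names(hz) <- paste0("h", horizon_hours)
  c(hz,
    list(aw = c(wake, rating_time),
         as = c(last$onset, last$wake),
         wake = wake, onset = last$onset))
}

# ---- IBI cleaning & Poincare ------------------------------------------------

#' Clean one window of inter-beat intervals
#'
#' An interval is flagged as an artifact when it deviates by more than
#' `rel_dev` from the median of the five preceding accepted intervals
#' (Malik-style rule). Up to `max_artifacts - 1` artifacts are replaced by
#' linear interpolation of the neighbouring accepted values; windows with
#' `max_artifacts` or more artifacts, or fewer than `min_n` beats, are
#' rejected.
#'
#' @param ibis numeric vector of inter-beat intervals, ms, time ordered.
#' @param rel_dev relative deviation flagging an artifact.
#' @param max_artifacts rejection count.
#' @param min_n minimum number of beats.
#' @return list with `ok` (logical), `ibis` (cleaned values when `ok`),
#'   `n_interpolated`, and `reason` when rejected.
#' @export
clean_ibi_window <- function(ibis, rel_dev = 0.25, max_artifacts = 4L,
                             min_n = 10L) {
  if (any(ibis <= 0)) stopf("inter-beat intervals must be positive")
  n <- length(ibis)
  if (n < min_n) {
    return(list(ok = FALSE, ibis = NULL, n_interpolated = NA_integer_,
                reason = "insufficient beats"))
  }
  artifact <- seq_artifacts(ibis, rel_dev)
  n_art <- sum(artifact)
  if (n_art >= max_artifacts) {
    return(list(ok = FALSE, ibis = NULL, n_interpolated = n_art,
                reason = "too many artifacts"))
  }
  out <- ibis
  if (n_art > 0L) {
    good <- which(!artifact)
    out[artifact] <- stats::approx(good, ibis[good], xout = which(artifact),
                                   rule = 2)$y
  }
  list(ok = TRUE, ibis = out, n_interpolated = n_art, reason = NULL)
}

#' Poincare heart-rate-variability metrics
#'
#' SDNN is the population standard deviation of the intervals. SD1 is the
#' root-mean-square perpendicular distance of consecutive interval pairs to
#' the identity line of the Poincare plot, `sqrt(mean(((x - y)/sqrt(2))^2))`,
#' which makes `SD1 = RMSSD / sqrt(2)` an exact identity. SD2 is the
#' population SD of the along-line coordinate `(x + y)/sqrt(2)`.
#'
#' @param ibis cleaned inter-beat intervals, ms (at least 10).
#' @return list with `sdnn`, `sd1`, `sd2` (ms).
#' @export
poincare_metrics <- function(ibis) {
  if (length(ibis) < 10L) stopf("need at least 10 inter-beat intervals")
  x <- ibis[-length(ibis)]
  y <- ibis[-1]
  list(sdnn = pop_sd(ibis),
       sd1 = sqrt(mean(((x - y) / sqrt(2))^2)),
       sd2 = pop_sd((x + y) / sqrt(2)))
}

# Sequential artifact flags: deviation > rel_dev from the median of the
# (up to) five preceding accepted intervals. `from`/`buf0` let a caller
# resume mid-window when a prefix is already known to be clean.
seq_artifacts <- function(ibis, rel_dev, from = 1L, buf0 = numeric(0)) {
  n <- length(ibis)
  artifact <- logical(n)
  buf <- numeric(5)
  k <- min(length(buf0), 5L)
  if (k > 0L) buf[seq_len(k)] <- utils::tail(buf0, 5L)
  for (i in from:n) {
    if (k > 0L) {
      ref <- median_small(buf[seq_len(k)])
      if (abs(ibis[i] - ref) / ref > rel_dev) {
        artifact[i] <- TRUE
        next
      }
    }
    if (k < 5L) {
      k <- k + 1L
      buf[k] <- ibis[i]
    } else {
      buf[1:4] <- buf[2:5]
      buf[5] <- ibis[i]
    }
  }
  artifact
}

# median of <= 5 values via comparison networks (no sort dispatch)
median_small <- function(w) {
  k <- length(w)
  if (k == 1L) return(w[1])
  if (k == 2L) return((w[1] + w[2]) / 2)
  if (k == 3L) return(max(min(w[1], w[2]), min(max(w[1], w[2]), w[3])))
  if (k == 4L) return((w[1] + w[2] + w[3] + w[4] - min(w) - max(w)) / 2)
  lo <- max(min(w[1], w[2]), min(w[3], w[4]))
  hi <- min(max(w[1], w[2]), max(w[3], w[4]))
  max(min(lo, hi), min(max(lo, hi), w[5]))
}

# vectorized median-of-5 (classic comparison network)
median5 <- function(a, b, c, d, e) {
  lo <- pmax(pmin(a, b), pmin(c, d))
  hi <- pmin(pmax(a, b), pmax(c, d))
  pmax(pmin(lo, hi), pmin(pmax(lo, hi), e))
}

# Fast path for clean_ibi_window: a vectorized screen against the rolling
# median of the five preceding *raw* intervals. If no beat is flagged, the
# sequential accepted-median rule provably flags none either (inductively the
# accepted buffer equals the raw history), so the window is clean; otherwise
# fall back to the exact sequential rule.
clean_ibi_fast <- function(ibis, rel_dev, max_artifacts, min_n) {
  n <- length(ibis)
  if (n < min_n) {
    return(list(ok = FALSE, ibis = NULL, n_interpolated = NA_integer_,
                reason = "insufficient beats"))
  }
  f0 <- 0L
  for (i in 2:min(5L, n)) {
    ref <- median_small(ibis[seq_len(i - 1L)])
    if (abs(ibis[i] - ref) / ref > rel_dev) {
      f0 <- i
      break
    }
  }
  if (f0 == 0L && n >= 6L) {
    E <- embed(ibis, 6L)  # row i: ibis[i+5], ibis[i+4], ..., ibis[i]
    ref <- median5(E[, 6], E[, 5], E[, 4], E[, 3], E[, 2])
    hits <- which(abs(E[, 1] - ref) / ref > rel_dev)
    if (length(hits)) f0 <- hits[1] + 5L
  }
  if (f0 == 0L) {
    return(list(ok = TRUE, ibis = ibis, n_interpolated = 0L, reason = NULL))
  }
  # the prefix before the first raw-median flag is provably accepted; resume
  # the exact sequential rule there
  artifact <- seq_artifacts(ibis, rel_dev, from = f0,
                            buf0 = ibis[seq_len(f0 - 1L)])
  n_art <- sum(artifact)
  if (n_art >= max_artifacts) {
    return(list(ok = FALSE, ibis = NULL, n_interpolated = n_art,
                reason = "too many artifacts"))
  }
  out <- ibis
  if (n_art > 0L) {
    good <- which(!artifact)
    out[artifact] <- stats::approx(good, ibis[good], xout = which(artifact),
                                   rule = 2)$y
  }
  list(ok = TRUE, ibis = out, n_interpolated = n_art, reason = NULL)
}

# ---- rest windows -----------------------------------------------------------

# Rest windows for a whole recording on the global 5-min grid. Each window
# must satisfy: mean HR below rest_hr_fraction * (220 - age); population SD
# of acceleration below motion_sd_threshold; >= min beats; < max_artifact
# flagged inter-beat intervals. Returns one row per accepted window with its
# Poincare metrics and the cleaned beat list (list column `ibis`).
compute_rest_windows <- function(hr, acc, ibi, age, config,
                                 range = NULL) {
  if (is.null(range)) {
    range <- c(min(hr$time, acc$time), max(hr$time, acc$time))
  }
  w0 <- floor(range[1] / .WIN)
  w1 <- ceiling(range[2] / .WIN) - 1L
  if (w1 < w0) return(empty_rest_windows())
  nw <- w1 - w0 + 1L
  to_arr <- function(tv) {
    arr <- rep(NA_real_, nw)
    idx <- as.integer(names(tv)) - w0 + 1L
    ok <- idx >= 1L & idx <= nw
    arr[idx[ok]] <- as.numeric(tv)[ok]
    arr
  }
  hr_w <- floor(hr$time / .WIN)
  acc_w <- floor(acc$time / .WIN)
  hr_mean <- to_arr(tapply(hr$value, hr_w, mean))
  hr_n <- to_arr(tapply(hr$value, hr_w, length))
  acc_sd <- to_arr(tapply(acc$value, acc_w, pop_sd))
  acc_n <- to_arr(tapply(acc$value, acc_w, length))
  hr_max <- config$rest_hr_fraction * (220 - age)
  min_samp <- max(3, floor(.WIN * config$sampling_rate * 0.6))
  # beats are time-sorted, so each window's beats form a contiguous run
  iw <- floor(ibi$time / .WIN)
  ikeep <- iw >= w0 & iw <= w1
  iv <- ibi$value[ikeep]
  icnt <- tabulate(iw[ikeep] - w0 + 1L, nbins = nw)
  iend <- cumsum(icnt)
  istart <- iend - icnt + 1L
  rows <- list()
  for (w in w0:w1) {
    j <- w - w0 + 1L
    hm <- hr_mean[j]; hn <- hr_n[j]
    as_ <- acc_sd[j]; an <- acc_n[j]
    if (is.na(hm) || is.na(hn) || hn < min_samp || hm >= hr_max) next
    if (is.na(as_) || is.na(an) || an < min_samp || as_ >= config$motion_sd_threshold) next
    start <- w * .WIN; end <- start + .WIN
    sel <- if (icnt[j]) iv[istart[j]:iend[j]] else numeric(0)
    cl <- clean_ibi_fast(sel, rel_dev = config$artifact_rel_dev,
                         max_artifacts = config$max_artifact_ibis,
                         min_n = config$min_ibis_per_window)
    if (!cl$ok) next
    pm <- poincare_metrics(cl$ibis)
    rows[[length(rows) + 1L]] <- list(
      start = start, end = end, mean_hr = as.numeric(hm),
      acc_sd = as.numeric(as_), n_interpolated = cl$n_interpolated,
      sdnn = pm$sdnn, sd1 = pm$sd1, sd2 = pm$sd2, ibis = cl$ibis)
  }
  if (!length(rows)) return(empty_rest_windows())
  out <- data.frame(
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    mean_hr = vapply(rows, `[[`, 0, "mean_hr"),
    acc_sd = vapply(rows, `[[`, 0, "acc_sd"),
    n_interpolated = vapply(rows, `[[`, 0L, "n_interpolated"),
    sdnn = vapply(rows, `[[`, 0, "sdnn"),
    sd1 = vapply(rows, `[[`, 0, "sd1"),
    sd2 = vapply(rows, `[[`, 0, "sd2"))
  out$ibis <- lapply(rows, `[[`, "ibis")
  out
}

empty_rest_windows <- function() {
  out <- data.frame(start = numeric(0), end = numeric(0),
                    mean_hr = numeric(0), acc_sd = numeric(0),
                    n_interpolated = integer(0), sdnn = numeric(0),
                    sd1 = numeric(0), sd2 = numeric(0))
  out$ibis <- list()
  out
}

#' Detect 5-minute rest windows inside one horizon
#'
#' Windows are tiled on a 5-minute grid; a window qualifies when the mean
#' heart rate stays below `rest_hr_fraction * (220 - age)`, the acceleration
#' magnitude shows no measurable continuous motion (population SD below
#' `motion_sd_threshold`), and its beat list passes [clean_ibi_window()].
#' An empty result is valid: the horizon then contributes no
#' heart-rate-variability features.
#'
#' @param hr,acc,ibi channel data.frames (`time`, `value`).
#' @param age participant age in years.
#' @param horizon `c(start, end)` in seconds.
#' @param config a [run_config()].
#' @return data.frame of accepted windows (possibly 0 rows) with the window
#'   bounds, mean HR, acceleration SD, interpolation count, Poincare metrics
#'   and cleaned beat lists.
#' @export
detect_rest_windows <- function(hr, acc, ibi, age, horizon,
                                config = run_config()) {
  if (horizon[2] <= horizon[1]) stopf("horizon must be non-empty")
  win <- compute_rest_windows(hr, acc, ibi, age, config, range = horizon)
  win[win$start >= horizon[1] & win$end <= horizon[2], , drop = FALSE]
}

#' Independently re-check emitted rest windows
#'
#' Brute-force auditor: for every emitted window it recomputes, directly from
#' the raw channels and by a literal re-application of the rest rules, the
#' mean-HR criterion, the motion criterion, the beat count, and the
#' artifact-count rule. Intended for tests: returns per-window pass flags.
#'
#' @param windows data.frame from [detect_rest_windows()].
#' @param bundle the [sensor_bundle()] the windows came from.
#' @param config the [run_config()] used.
#' @return logical vector, one entry per window; TRUE = window obeys every rule.
#' @export
audit_rest_windows <- function(windows, bundle, config = run_config()) {
  if (nrow(windows) == 0L) return(logical(0))
  # channel times are sorted, so [start, end) slices can be located by one
  # vectorized binary search per channel; the gating rules below are still
  # re-applied from scratch
  mk_slicer <- function(df) {
    lo <- findInterval(windows$start - 1e-9, df$time)
    hi <- findInterval(windows$end - 1e-9, df$time)
    function(i) if (hi[i] > lo[i]) df$value[(lo[i] + 1L):hi[i]] else numeric(0)
  }
  hr_slice <- mk_slicer(bundle$hr)
  acc_slice <- mk_slicer(bundle$acc)
  ibi_slice <- mk_slicer(bundle$ibi)
  vapply(seq_len(nrow(windows)), function(i) {
    hr_v <- hr_slice(i)
    acc_v <- acc_slice(i)
    if (!length(hr_v) || mean(hr_v) >= config$rest_hr_fraction * (220 - bundle$age)) {
      return(FALSE)
    }
    m <- mean(acc_v)
    if (!length(acc_v) ||
        sqrt(sum((acc_v - m)^2) / length(acc_v)) >= config$motion_sd_threshold) {
      return(FALSE)
    }
    raw <- ibi_slice(i)
    if (length(raw) < config$min_ibis_per_window) return(FALSE)
    # literal sequential artifact count
    n_art <- 0L
    accepted <- numeric(0)
    for (v in raw) {
      if (length(accepted)) {
        ref <- stats::median(utils::tail(accepted, 5L))
        if (abs(v - ref) / ref > config$artifact_rel_dev) {
          n_art <- n_art + 1L
          next
        }
      }
      accepted <- c(accepted, v)
    }
    n_art < config$max_artifact_ibis && n_art == windows$n_interpolated[i]
  }, logical(1))
}

# ---- per-horizon aggregation ------------------------------------------------

#' Aggregate a timed series over one horizon
#'
#' Returns the minimum, maximum, mean, population SD and the ordinary
#' least-squares slope (units per hour) of the values falling inside the
#' horizon. SD and slope require at least two values (slope additionally two
#' distinct times); the rest require at least one; unavailable statistics
#' are `NA`.
#'
#' @param times,values the series (seconds, values).
#' @param horizon `c(start, end)` seconds.
#' @return named list `min`, `max`, `mean`, `sd`, `slope`.
#' @export
aggregate_stats <- function(times, values, horizon) {
  if (horizon[2] <= horizon[1]) stopf("horizon must be non-empty")
  sel <- times >= horizon[1] & times < horizon[2]
  t <- times[sel]; v <- values[sel]
  keep <- !is.na(v)
  t <- t[keep]; v <- v[keep]
  n <- length(v)
  out <- list(min = NA_real_, max = NA_real_, mean = NA_real_,
              sd = NA_real_, slope = NA_real_)
  if (n >= 1L) {
    out$min <- min(v); out$max <- max(v); out$mean <- mean(v)
  }
  if (n >= 2L) {
    out$sd <- pop_sd(v)
    tc <- t - mean(t)
    if (sum(tc^2) > 0) {
      out$slope <- sum(tc * (v - mean(v))) / sum(tc^2) * .HOUR
    }
  }
  out
}

#' Count electrodermal peaks in a horizon
#'
#' A peak is a local maximum of the baseline-subtracted signal (centred
#' moving average of width `config$eda_baseline_window` seconds) whose height
#' above baseline reaches `config$eda_prominence`. Also returns peak counts
#' per 5-minute subwindow (for the variability-of-peak-counts feature).
#'
#' @param eda data.frame (`time`, `value`).
#' @param horizon `c(start, end)` seconds.
#' @param config a [run_config()].
#' @return list `count`, `sub_counts` (per full 5-min tile inside the
#'   horizon), `peak_times`.
#' @export
count_eda_peaks <- function(eda, horizon, config = run_config()) {
  if (horizon[2] <= horizon[1]) stopf("horizon must be non-empty")
  sel <- eda$time >= horizon[1] & eda$time < horizon[2]
  t <- eda$time[sel]; v <- eda$value[sel]
  pk_t <- numeric(0)
  if (length(v) >= 5L) {
    dt <- stats::median(diff(t))
    w <- max(3L, round(config$eda_baseline_window / dt))
    w <- min(w, length(v))
    if (w %% 2L == 0L) w <- w - 1L
    filt <- v - runmean(v, w)
    pk <- pracma::findpeaks(filt, minpeakheight = config$eda_prominence)
    if (!is.null(pk)) pk_t <- t[pk[, 2]]
  }
  tiles0 <- ceiling(horizon[1] / .WIN)
  tiles1 <- floor(horizon[2] / .WIN) - 1L
  sub <- if (tiles1 >= tiles0) {
    vapply(tiles0:tiles1, function(w) {
      sum(pk_t >= w * .WIN & pk_t < (w + 1L) * .WIN)
    }, numeric(1))
  } else numeric(0)
  list(count = length(pk_t), sub_counts = sub, peak_times = pk_t)
}

#' Physical-activity features for one horizon
#'
#' Acceleration-magnitude statistics, the trapezoidal integral of the
#' magnitude (acceleration x hours, with constant extension to the horizon
#' edges), and the step count summed over the horizon with step intervals
#' straddling an edge prorated by overlap.
#'
#' @param acc data.frame (`time`, `value`).
#' @param steps data.frame (`time` = interval start, `value` = count).
#' @param horizon `c(start, end)` seconds.
#' @param step_interval step-interval width, seconds.
#' @return named list `mean`, `min`, `max`, `sd`, `int`, `steps`.
#' @export
activity_features <- function(acc, steps, horizon, step_interval = 60) {
  if (horizon[2] <= horizon[1]) stopf("horizon must be non-empty")
  sel <- acc$time >= horizon[1] & acc$time < horizon[2]
  t <- acc$time[sel]; v <- acc$value[sel]
  out <- list(mean = NA_real_, min = NA_real_, max = NA_real_,
              sd = NA_real_, int = NA_real_, steps = NA_real_)
  if (length(v) >= 1L) {
    out$mean <- mean(v); out$min <- min(v); out$max <- max(v)
    out$sd <- if (length(v) >= 2L) pop_sd(v) else NA_real_
    tt <- c(horizon[1], t, horizon[2])
    vv <- c(v[1], v, v[length(v)])
    out$int <- pracma::trapz(tt / .HOUR, vv)
  }
  if (nrow(steps)) {
    ov <- interval_overlap(steps$time, steps$time + step_interval,
                           horizon[1], horizon[2])
    out$steps <- sum(steps$value * ov / step_interval)
  }
  out
}

#' Daily-routine features for one rating
#'
#' Time of day (hours), time awake since the last wake (hours), duration of
#' the prior night's sleep (hours), and how much later than the study-average
#' clock time the participant woke up (`wake_dev`) and went to bed
#' (`bed_dev`), in hours.
#'
#' @param rating_time rating time, seconds.
#' @param schedule a [estimate_sleep_wake()] schedule.
#' @return named list; sleep-derived entries are `NA` when no completed
#'   night precedes the rating.
#' @export
routine_features <- function(rating_time, schedule) {
  out <- list(time_of_day = (rating_time %% .DAY) / .HOUR,
              time_awake = NA_real_, sleep_duration = NA_real_,
              wake_dev = NA_real_, bed_dev = NA_real_)
  done <- schedule[schedule$wake <= rating_time, , drop = FALSE]
  if (nrow(done) == 0L) return(out)
  last <- done[which.max(done$wake), ]
  out$time_awake <- (rating_time - last$wake) / .HOUR
  out$sleep_duration <- (last$wake - last$onset) / .HOUR
  # clock positions on scales without midnight wrap: onsets relative to noon,
  # wakes relative to midnight
  onset_clock <- ((schedule$onset - 12 * .HOUR) %% .DAY) / .HOUR
  wake_clock <- (schedule$wake %% .DAY) / .HOUR
  this_onset <- ((last$onset - 12 * .HOUR) %% .DAY) / .HOUR
  this_wake <- (last$wake %% .DAY) / .HOUR
  out$wake_dev <- this_wake - mean(wake_clock)
  out$bed_dev <- this_onset - mean(onset_clock)
  out
}

#' Day-level weather features for one rating
#'
#' Weather is recorded daily; every rating of a day gets the same values.
#'
#' @param weather data.frame with columns `day`, `temp_mean`, `temp_min`,
#'   `felttemp_min`, `dew_mean`, `humidity_mean`.
#' @param rating_time rating time, seconds (day = `floor(time / 86400)`).
#' @return named list of the five weather features (`NA` if the day is
#'   missing from the record).
#' @export
weather_features <- function(weather, rating_time) {
  d <- floor(rating_time / .DAY)
  row <- weather[weather$day == d, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(list(temp_day_mean = NA_real_, temp_day_min = NA_real_,
                felttemp_day_min = NA_real_, dew_day_mean = NA_real_,
                humidity_day_mean = NA_real_))
  }
  list(temp_day_mean = row$temp_mean[1], temp_day_min = row$temp_min[1],
       felttemp_day_min = row$felttemp_min[1], dew_day_mean = row$dew_mean[1],
       humidity_day_mean = row$humidity_mean[1])
}

# ---- assembly ---------------------------------------------------------------

#' Assemble the feature table for one participant
#'
#' Runs the full extraction for every rating: builds the five horizons from
#' the sleep schedule, computes rest-window heart-rate-variability, heart
#' rate, electrodermal, skin-temperature, activity, routine and weather
#' features, and records a missingness mask per feature. Ratings that fall
#' inside a detected sleep interval are excluded with a warning.
#'
#' @param bundle a [sensor_bundle()].
#' @param ratings data.frame with `rating_id`, `time` (s), `vas`.
#' @param schedule sleep schedule (from [estimate_sleep_wake()] or the
#'   generator's truth).
#' @param weather daily weather data.frame (see [weather_features()]).
#' @param config a [run_config()].
#' @return a [feature_table()] with attributes `rest_windows` (all accepted
#'   windows, for auditing) and `schedule`.
#' @export
assemble_features <- function(bundle, ratings, schedule, weather,
                              config = run_config()) {
  census <- feature_census()
  wins <- compute_rest_windows(bundle$hr, bundle$acc, bundle$ibi,
                               bundle$age, config)
  hr_min <- minute_means(bundle$hr)
  eda_min <- minute_means(bundle$eda)
  temp_min <- minute_means(bundle$temp)
  wmid <- (wins$start + wins$end) / 2

  rows <- vector("list", nrow(ratings))
  keep <- logical(nrow(ratings))
  for (i in seq_len(nrow(ratings))) {
    rt <- ratings$time[i]
    asleep_now <- any(schedule$onset < rt & rt < schedule$wake)
    if (asleep_now) {
      warnf("rating %s falls inside a detected sleep interval; excluded",
            ratings$rating_id[i])
      next
    }
    if (!any(schedule$wake <= rt)) next  # before first wake: no horizons yet
    hz <- build_horizons(rt, schedule, config$horizon_hours)
    ivs <- list(`1h` = hz$h1, `3h` = hz$h3, `6h` = hz$h6,
                aw = hz$aw, as = hz$as)
    f <- list()
    for (k in .HORIZON_KEYS) {
      iv <- ivs[[k]]
      if (is.null(iv) || iv[2] <= iv[1]) {
        # horizon unavailable: leave every feature of this horizon NA
        next
      }
      st <- aggregate_stats(hr_min$time, hr_min$value, iv)
      for (s in names(st)) f[[paste("hr", k, s, sep = "_")]] <- st[[s]]
      inwin <- wmid >= iv[1] & wins$end <= iv[2] & wins$start >= iv[1]
      for (m in c("sdnn", "sd1", "sd2")) {
        st <- aggregate_stats(wmid[inwin], wins[[m]][inwin], iv)
        for (s in names(st)) f[[paste(m, k, s, sep = "_")]] <- st[[s]]
      }
      st <- aggregate_stats(eda_min$time, eda_min$value, iv)
      for (s in names(st)) f[[paste("eda", k, s, sep = "_")]] <- st[[s]]
      pk <- count_eda_peaks(bundle$eda, iv, config)
      f[[paste("eda_peaks", k, "count", sep = "_")]] <- pk$count
      f[[paste("eda_peaks", k, "sd", sep = "_")]] <-
        if (length(pk$sub_counts) >= 2L) pop_sd(pk$sub_counts) else NA_real_
      st <- aggregate_stats(temp_min$time, temp_min$value, iv)
      for (s in names(st)) f[[paste("temp", k, s, sep = "_")]] <- st[[s]]
      act <- activity_features(bundle$acc, bundle$steps, iv,
                               bundle$step_interval)
      for (s in c("mean", "min", "max", "sd", "int")) {
        f[[paste("acc", k, s, sep = "_")]] <- act[[s]]
      }
      f[[paste("steps", k, "count", sep = "_")]] <- act$steps
    }
    rf <- routine_features(rt, schedule)
    f <- c(f, rf, weather_features(weather, rt))
    # fill the census: anything not computed is missing
    vals <- stats::setNames(rep(NA_real_, nrow(census)), census$name)
    got <- intersect(names(f), census$name)
    vals[got] <- unlist(f[got])
    rows[[i]] <- vals
    keep[i] <- TRUE
  }
  kept <- which(keep)
  mat <- if (length(kept)) do.call(rbind, rows[kept]) else
    matrix(numeric(0), 0, nrow(census), dimnames = list(NULL, census$name))
  df <- data.frame(rating_id = ratings$rating_id[kept],
                   participant_id = rep(bundle$id, length(kept)),
                   rating_time = ratings$time[kept],
                   vas = ratings$vas[kept],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mat))
  ft <- feature_table(df, feature_names = census$name)
  attr(ft, "rest_windows") <- wins
  attr(ft, "schedule") <- schedule
  ft
}

# Bind per-participant feature tables into one cohort table.
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  fn <- feature_names(tables[[1]])
  df <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(df) <- NULL
  feature_table(df, feature_names = fn)
}
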