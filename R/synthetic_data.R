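# Seeded synthetic cohorts: raw sensor streams, sleep schedules, weather and
# VAS ratings produced from a known additive ground-truth model over the
# *extracted* features. Ratings are generated in two stages (streams ->
# extracted features -> ratings) so the extractor and the generator can never
# disagree about what a feature value is.

#' Cohort specification
#'
#' Study-shaped defaults: 14 recording days, on average 3.8 ratings per
#' participant-day, about a quarter of the feature vectors incomplete.
#'
#' @param n_co,n_ms1,n_ms2 participants per group (healthy controls, patients
#'   with a functional autonomic nervous system, patients with a
#'   dysfunctional one).
#' @param days rating days per participant.
#' @param ratings_per_day mean ratings per day (Poisson).
#' @param missing_rate target fraction of incomplete feature vectors.
#' @param noise_sd rating noise on the normalized-fatigue scale.
#' @param seed master seed; the cohort is a pure function of (spec, truth).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_co = 23L, n_ms1 = 27L, n_ms2 = 24L, days = 14L,
                        ratings_per_day = 3.8, missing_rate = 0.25,
                        noise_sd = 0.8, seed = 1L) {
  if (min(n_co, n_ms1, n_ms2) < 0L) stopf("participant counts must be >= 0")
  if (days < 1L) stopf("days must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  structure(list(n_co = as.integer(n_co), n_ms1 = as.integer(n_ms1),
                 n_ms2 = as.integer(n_ms2), days = as.integer(days),
                 ratings_per_day = ratings_per_day,
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# shape -> bounded effect function of a normalized feature
shape_fun <- function(shape) {
  switch(shape,
         inc = function(x) tanh(x),
         dec = function(x) -tanh(x),
         concave = function(x) exp(-x^2 / 2) - 0.5,
         convex = function(x) 0.5 - exp(-x^2 / 2),
         linear = function(x) x,
         flat = function(x) rep(0, length(x)),
         stopf("unknown effect shape '%s'", shape))
}

#' Ground-truth additive model
#'
#' Per group, a set of bounded effect functions on normalized features, plus
#' an optional linear intercept trend over the time of day and the rating
#' noise. Effect shapes: `inc`/`dec` (monotone, `a*tanh(x)`), `concave`
#' (rise-then-fall), `convex`, `linear`, `flat`.
#'
#' @param effects named list (`CO`, `MS_I`, `MS_II`), each a data.frame with
#'   columns `feature`, `shape`, `amplitude`.
#' @param noise_sd rating noise SD on the normalized scale.
#' @param trend_per_hour latent increase per hour of the day (applied to all
#'   groups through the time of day).
#' @return object of class `truth_model`.
#' @export
truth_model <- function(effects, noise_sd = 0.8, trend_per_hour = 0) {
  census <- feature_census()$name
  for (g in names(effects)) {
    ef <- effects[[g]]
    bad <- setdiff(ef$feature, census)
    if (length(bad)) {
      stopf("truth references a feature the extractor does not produce: %s",
            bad[1])
    }
    for (s in ef$shape) shape_fun(s)  # errors on unknown shape labels
  }
  structure(list(effects = effects, noise_sd = noise_sd,
                 trend_per_hour = trend_per_hour),
            class = "truth_model")
}

#' Default ground truth
#'
#' Group-specific effect sets with the direction structure reported for this
#' kind of cohort: time of day rises fatigue for controls and patients with a
#' dysfunctional autonomic nervous system, time awake for the functional-ANS
#' patients, heart rate while asleep rises it for the dysfunctional-ANS
#' group, and each group carries its own mix of heart-rate-variability,
#' activity, electrodermal and weather effects.
#'
#' @param noise_sd rating noise SD (normalized units).
#' @return a [truth_model()].
#' @export
default_truth_model <- function(noise_sd = 0.8) {
  ef <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(feature = m[, 1], shape = m[, 2],
               amplitude = as.numeric(m[, 3]))
  }
  truth_model(list(
    CO = ef("time_of_day", "inc", 0.55,
            "sdnn_6h_mean", "inc", 0.35,
            "sd1_3h_min", "dec", 0.30,
            "steps_6h_count", "dec", 0.30,
            "dew_day_mean", "dec", 0.25),
    MS_I = ef("time_awake", "inc", 0.55,
              "sleep_duration", "dec", 0.35,
              "sdnn_aw_max", "dec", 0.30,
              "acc_as_max", "inc", 0.30,
              "temp_day_mean", "dec", 0.25),
    MS_II = ef("time_of_day", "inc", 0.50,
               "hr_as_mean", "inc", 0.40,
               "sd1_3h_mean", "inc", 0.30,
               "sdnn_1h_sd", "inc", 0.30,
               "eda_peaks_1h_sd", "inc", 0.30,
               "humidity_day_mean", "inc", 0.25)),
    noise_sd = noise_sd, trend_per_hour = 0.03)
}

#' Tabulate a truth model on a grid (for the truth record)
#'
#' @param truth a [truth_model()].
#' @param grid normalized feature grid.
#' @return list per group of data.frames `feature`, `shape`, plus matrix of
#'   effect values on the grid.
#' @export
tabulate_truth <- function(truth, grid = seq(-2.5, 2.5, length.out = 41)) {
  lapply(truth$effects, function(ef) {
    vals <- vapply(seq_len(nrow(ef)), function(i) {
      ef$amplitude[i] * shape_fun(ef$shape[i])(grid)
    }, numeric(length(grid)))
    list(features = ef, grid = grid,
         values = matrix(vals, ncol = nrow(ef),
                         dimnames = list(NULL, ef$feature)))
  })
}

# ---- participants, schedules, weather --------------------------------------

generate_participants <- function(spec) {
  with_seed(child_seed(spec$seed, "participants"), {
    mk <- function(n, prefix, group) {
      if (n == 0L) return(NULL)
      age <- round(stats::runif(n, 20, 60))
      sex <- sample(c("f", "m"), n, replace = TRUE)
      compass <- switch(group,
                        CO = stats::runif(n, 0, 10),
                        MS_I = stats::runif(n, 2, 17),
                        MS_II = stats::runif(n, 18, 45))
      pmean <- switch(group,
                      CO = stats::rnorm(n, 3.8, 1.0),
                      MS_I = stats::rnorm(n, 3.6, 1.4),
                      MS_II = stats::rnorm(n, 4.5, 1.5))
      pmean <- pmin(pmax(pmean, 1.8), 8)
      psd <- pmax(stats::rnorm(n, 1.5, 0.2), 1.0)
      fsmc <- if (group == "CO") rep(NA_real_, n) else
        pmin(pmax(14 * pmean + stats::rnorm(n, 0, 15), 15), 100)
      data.frame(id = sprintf("%s%02d", prefix, seq_len(n)), group = group,
                 age = age, sex = sex, compass = round(compass, 1),
                 fsmc = round(fsmc, 1), vas_mean = pmean, vas_sd = psd,
                 stringsAsFactors = FALSE)
    }
    rbind(mk(spec$n_co, "co", "CO"), mk(spec$n_ms1, "ms1_", "MS_I"),
          mk(spec$n_ms2, "ms2_", "MS_II"))
  })
}

# one main sleep period per night: onset ~ 23:00 +- 1 h, duration ~ 8 +- 1 h
generate_sleep_schedule <- function(days, seed) {
  with_seed(seed, {
    nights <- 0:(days - 1L)
    onset <- nights * .DAY + 23 * .HOUR +
      pmin(pmax(stats::rnorm(days, 0, 0.75), -1.5), 1.5) * .HOUR
    dur <- pmin(pmax(stats::rnorm(days, 8, 0.75), 6.5), 9.5) * .HOUR
    sched <- data.frame(night = nights,
                        onset = round(onset / .MIN) * .MIN,
                        wake = round((onset + dur) / .MIN) * .MIN)
    class(sched) <- c("sleep_schedule", "data.frame")
    sched
  })
}

generate_weather <- function(days, seed) {
  with_seed(seed, {
    d <- 0:days
    tm <- stats::rnorm(length(d), 15, 6)
    tmin <- tm - stats::runif(length(d), 3, 8)
    data.frame(day = d,
               temp_mean = round(tm, 1),
               temp_min = round(tmin, 1),
               felttemp_min = round(tmin - stats::runif(length(d), 0, 3), 1),
               dew_mean = round(stats::rnorm(length(d), 8, 3), 1),
               humidity_mean = round(pmin(pmax(stats::rnorm(length(d), 70, 10), 30), 100), 1))
  })
}

# ---- channel generators -----------------------------------------------------

#' Generate an inter-beat-interval series with target Poincare statistics
#'
#' Stationary AR(1) Gaussian model on the intervals: the marginal SD sets
#' SDNN and the lag-1 correlation `phi = 1 - (sd1/sdnn)^2` sets SD1
#' (`SD1 = sdnn * sqrt(1 - phi)` for an AR(1)). A 10-minute realization
#' recovers the targets within roughly 15 percent.
#'
#' @param profile list with `mean_ibi` (ms), `sdnn` (ms), `sd1` (ms).
#' @param duration length of the series, seconds.
#' @param seed integer seed.
#' @return data.frame `time` (event time, s), `value` (ms).
#' @export
generate_ibi_series <- function(profile, duration, seed = 1L) {
  m <- profile$mean_ibi; sdnn <- profile$sdnn; sd1 <- profile$sd1
  if (duration <= 0) return(data.frame(time = numeric(0), value = numeric(0)))
  if (sdnn < 0 || sd1 < 0) stopf("targets must be non-negative")
  if (sdnn == 0) {
    n <- floor(duration * 1000 / m)
    return(data.frame(time = cumsum(rep(m, n)) / 1000, value = rep(m, n)))
  }
  phi <- 1 - (sd1 / sdnn)^2
  if (phi <= -1 || phi >= 1) {
    stopf("infeasible target pair: need 0 < sd1 < sdnn * sqrt(2) (got sd1=%g, sdnn=%g)",
          sd1, sdnn)
  }
  with_seed(seed, {
    n <- ceiling(duration * 1000 / m * 1.2) + 20L
    e <- stats::rnorm(n, 0, sdnn * sqrt(1 - phi^2))
    x <- as.numeric(stats::filter(e, phi, method = "recursive"))
    ibi <- pmax(m + x, 200)
    t <- cumsum(ibi) / 1000
    keep <- t <= duration
    data.frame(time = t[keep], value = ibi[keep])
  })
}

# full raw-stream synthesis for one participant
generate_streams <- function(age, schedule, days, config, seed) {
  with_seed(seed, {
    dt <- 1 / config$sampling_rate
    end <- (days + 1) * .DAY
    t <- seq(0, end - dt, by = dt)
    n <- length(t)
    asleep <- rep(FALSE, n)
    for (i in seq_len(nrow(schedule))) {
      asleep[t >= schedule$onset[i] & t < schedule$wake[i]] <- TRUE
    }
    # physical activity: low rest baseline + bounded activity bouts while awake
    level <- ifelse(asleep, 0.005, 0.03)
    wake_bounds <- cbind(c(0, schedule$wake), c(schedule$onset, end))
    for (w in seq_len(nrow(wake_bounds))) {
      a <- wake_bounds[w, 1]; b <- wake_bounds[w, 2]
      if (b <= a) next
      nb <- stats::rpois(1, 1.8 * (b - a) / .HOUR)
      if (nb == 0) next
      bs <- stats::runif(nb, a, b)
      bd <- stats::runif(nb, 300, 900)
      bl <- stats::runif(nb, 0.3, 0.9)
      for (j in seq_len(nb)) {
        idx <- t >= bs[j] & t < bs[j] + bd[j] & !asleep
        level[idx] <- pmax(level[idx], bl[j])
      }
    }
    moving <- level > 0.1
    acc_noise <- ifelse(moving, 0.18 * level + 0.03, 0.008)
    acc <- abs(level + stats::rnorm(n, 0, acc_noise))
    steps <- ifelse(moving, stats::rpois(n, level * 110 * dt / .MIN),
                    stats::rpois(n, 0.02))
    # heart rate: wake baseline + activity response, lower while asleep
    base <- stats::rnorm(1, 74, 2.5)
    night_off <- stats::rnorm(days, 0, 1.5)
    night_idx <- pmin(pmax(floor((t - 12 * .HOUR) / .DAY), 0), days - 1) + 1
    lev_sm <- runmean(level, 5)
    hr <- ifelse(asleep, base - 18 + night_off[night_idx], base + 26 * lev_sm) +
      1.5 * sin(2 * pi * (t / .DAY - 0.3)) + stats::rnorm(n, 0, 1.2)
    # skin temperature: slow circadian sinusoid + noise
    temp <- 33 + 0.5 * sin(2 * pi * (t - 4 * .HOUR) / .DAY) +
      stats::rnorm(n, 0, 0.1)
    # electrodermal: tonic drift + Poisson-timed SCR bumps with exp decay
    tonic <- 2 + 0.3 * sin(2 * pi * (t - 8 * .HOUR) / .DAY)
    hour_idx <- floor(t / .HOUR) + 1
    hour_mult <- exp(stats::rnorm(max(hour_idx), 0, 0.6))
    rate_min <- ifelse(asleep, 1 / 60, 4 / 60) * hour_mult[hour_idx]
    n_ev <- stats::rpois(n, rate_min * dt / .MIN)
    ev_t <- rep(t, n_ev) + stats::runif(sum(n_ev), 0, dt)
    ev_a <- stats::runif(length(ev_t), 0.15, 0.5)
    eda <- tonic
    tau <- 120
    horizon_idx <- ceiling(10 * tau / dt)
    for (j in seq_along(ev_t)) {
      i0 <- findInterval(ev_t[j], t) + 1L
      if (i0 > n) next
      i1 <- min(i0 + horizon_idx, n)
      eda[i0:i1] <- eda[i0:i1] + ev_a[j] * exp(-(t[i0:i1] - ev_t[j]) / tau)
    }
    eda <- eda + stats::rnorm(n, 0, 0.01)
    # inter-beat intervals: AR(1) around 60000/HR with state-dependent SD
    sd_wake <- stats::rnorm(1, 45, 4)
    sd_sleep <- stats::rnorm(1, 62, 6)
    phi <- 0.55
    m_nom <- 60000 / mean(hr)
    nb <- ceiling(end * 1000 / m_nom * 1.15) + 10L
    t_nom <- (seq_len(nb) - 1) * m_nom / 1000
    hr_at <- stats::approx(t, hr, xout = pmin(t_nom, max(t)), rule = 2)$y
    asleep_at <- stats::approx(t, as.numeric(asleep), xout = pmin(t_nom, max(t)),
                               rule = 2)$y > 0.5
    sig <- ifelse(asleep_at, sd_sleep, sd_wake)
    u <- as.numeric(stats::filter(stats::rnorm(nb, 0, sqrt(1 - phi^2)), phi,
                                  method = "recursive"))
    ibi <- pmax(60000 / hr_at + sig * u, 250)
    art <- stats::runif(nb) < 0.0012
    ibi[art] <- ibi[art] * sample(c(1.7, 0.55), sum(art), replace = TRUE)
    ibi_t <- cumsum(ibi) / 1000
    keep <- ibi_t <= end
    list(hr = data.frame(time = t, value = hr),
         eda = data.frame(time = t, value = eda),
         temp = data.frame(time = t, value = temp),
         acc = data.frame(time = t, value = acc),
         ibi = data.frame(time = round(ibi_t[keep], 3), value = ibi[keep]),
         steps = data.frame(time = t, value = steps),
         step_interval = dt)
  })
}

# ---- ratings ----------------------------------------------------------------

generate_rating_times <- function(spec, schedule, seed) {
  with_seed(seed, {
    out <- list()
    for (d in seq_len(spec$days)) {
      prev <- schedule[schedule$night == d - 1L, ]
      if (nrow(prev) == 0L) next
      lo <- prev$wake + 10 * .MIN
      nx <- schedule[schedule$night == d, ]
      hi <- if (nrow(nx)) nx$onset - 10 * .MIN else d * .DAY + 23 * .HOUR
      if (hi <= lo) next
      nr <- stats::rpois(1, spec$ratings_per_day)
      if (nr == 0L) next
      out[[length(out) + 1L]] <- sort(stats::runif(nr, lo, hi))
    }
    unlist(out) %||% numeric(0)
  })
}

#' Generate VAS ratings from normalized features and a truth model
#'
#' Latent fatigue = sum of the group's effect functions evaluated at the
#' normalized feature values, plus the time-of-day trend, plus Gaussian
#' noise; the observed VAS is `clip(mean_p + sd_p * latent, 1, 10)` rounded
#' to 0.1, with `mean_p`/`sd_p` the participant's rating mean and SD.
#'
#' @param features normalized, complete [feature_table()] (missing cells are
#'   treated as 0 = the participant mean).
#' @param truth a [truth_model()].
#' @param participants data.frame with `id`, `group`, `vas_mean`, `vas_sd`.
#' @param seed integer seed for the noise.
#' @return data.frame `rating_id`, `participant_id`, `time`, `latent`,
#'   `vas`.
#' @export
generate_ratings <- function(features, truth, participants, seed = 1L) {
  df <- as.data.frame(features)
  n <- nrow(df)
  latent <- numeric(n)
  for (g in names(truth$effects)) {
    pid_g <- participants$id[participants$group == g]
    rows <- df$participant_id %in% pid_g
    if (!any(rows)) next
    ef <- truth$effects[[g]]
    for (i in seq_len(nrow(ef))) {
      x <- df[[ef$feature[i]]][rows]
      x[is.na(x)] <- 0
      latent[rows] <- latent[rows] +
        ef$amplitude[i] * shape_fun(ef$shape[i])(x)
    }
  }
  if (truth$trend_per_hour != 0) {
    tod <- (df$rating_time %% .DAY) / .HOUR
    latent <- latent + truth$trend_per_hour * (tod - 14)
  }
  with_seed(child_seed(seed, "rating-noise"), {
    latent_obs <- latent + stats::rnorm(n, 0, truth$noise_sd)
  })
  pm <- participants$vas_mean[match(df$participant_id, participants$id)]
  ps <- participants$vas_sd[match(df$participant_id, participants$id)]
  vas <- round(pmin(pmax(pm + ps * latent_obs, 1), 10), 1)
  data.frame(rating_id = df$rating_id, participant_id = df$participant_id,
             time = df$rating_time, latent = latent_obs, vas = vas,
             stringsAsFactors = FALSE)
}

#' Inject missingness into a raw recording
#'
#' Gaps are realized as motion bursts pasted into the hour before a random
#' subset of the participant's ratings (clipped at the wake time), so the
#' rest-window criterion fails there and cardiac features over the 1-hour
#' horizon go missing — the dominant missingness mode of arm-worn recordings.
#'
#' @param bundle a [sensor_bundle()].
#' @param ratings data.frame with the participant's rating `time`s.
#' @param schedule the participant's sleep schedule.
#' @param rate target fraction of incomplete feature vectors, in `[0, 1)`.
#' @param seed integer seed.
#' @return the modified [sensor_bundle()].
#' @export
inject_missingness <- function(bundle, ratings, schedule, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  n_hit <- floor(rate * nrow(ratings))
  if (n_hit == 0L) return(bundle)
  with_seed(child_seed(seed, paste0("miss-", bundle$id)), {
    hit <- sample(seq_len(nrow(ratings)), n_hit)
    for (i in hit) {
      rt <- ratings$time[i]
      done <- schedule[schedule$wake <= rt, , drop = FALSE]
      lo <- if (nrow(done)) max(rt - .HOUR, max(done$wake)) else rt - .HOUR
      idx <- bundle$acc$time >= lo & bundle$acc$time < rt
      k <- sum(idx)
      if (k == 0L) next
      bundle$acc$value[idx] <- abs(0.6 + stats::rnorm(k, 0, 0.25))
    }
  })
  bundle
}

# ---- cohort orchestration ---------------------------------------------------

#' Generate a full synthetic cohort
#'
#' Deterministic under `(spec, truth)`: participants, sleep schedules, raw
#' sensor streams, weather, rating times, features extracted from the clean
#' streams, ratings produced by the truth model on the normalized features,
#' and finally missingness injected into the streams. The returned truth
#' record keeps every effect function (tabulated) and the generation-time
#' feature table for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [truth_model()].
#' @param config a [run_config()].
#' @return list of class `synthetic_cohort` with elements `participants`,
#'   `bundles`, `schedules`, `weather`, `ratings`, `features` (generation
#'   time, normalized, pre-missingness), `truth`, `spec`, `config`.
#' @export
generate_cohort <- function(spec, truth = default_truth_model(spec$noise_sd),
                            config = run_config(seed = spec$seed)) {
  participants <- generate_participants(spec)
  if (is.null(participants) || nrow(participants) == 0L) {
    stopf("empty cohort: all group counts are zero")
  }
  weather <- generate_weather(spec$days, child_seed(spec$seed, "weather"))
  bundles <- list(); schedules <- list(); tables <- list(); rtimes <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$id[i]
    sched <- generate_sleep_schedule(spec$days, child_seed(spec$seed, paste0("sleep-", pid)))
    streams <- generate_streams(participants$age[i], sched, spec$days, config,
                                child_seed(spec$seed, paste0("streams-", pid)))
    bundle <- sensor_bundle(pid, participants$age[i], streams$hr, streams$eda,
                            streams$temp, streams$acc, streams$ibi,
                            streams$steps, step_interval = streams$step_interval)
    rt <- generate_rating_times(spec, sched, child_seed(spec$seed, paste0("rt-", pid)))
    ratings <- data.frame(rating_id = sprintf("%s_r%03d", pid, seq_along(rt)),
                          time = rt, vas = seq_along(rt) * 0.01 + 1,
                          stringsAsFactors = FALSE)
    tables[[pid]] <- assemble_features(bundle, ratings, sched, weather, config)
    bundles[[pid]] <- bundle
    schedules[[pid]] <- sched
    rtimes[[pid]] <- ratings
  }
  has_rows <- vapply(tables, nrow, 0L) > 0L
  if (!any(has_rows)) {
    empty <- tables[[1]]
    cohort <- list(participants = participants, bundles = bundles,
                   schedules = schedules, weather = weather,
                   ratings = data.frame(rating_id = character(0),
                                        participant_id = character(0),
                                        time = numeric(0), latent = numeric(0),
                                        vas = numeric(0)),
                   features = empty, truth = c(unclass(truth),
                                               list(tabulated = tabulate_truth(truth))),
                   spec = spec, config = config)
    class(cohort) <- "synthetic_cohort"
    return(cohort)
  }
  all_feat <- bind_feature_tables(tables[has_rows])
  norm <- suppressWarnings(normalize_per_participant(all_feat))
  ratings <- generate_ratings(norm$table, truth, participants,
                              seed = child_seed(spec$seed, "ratings"))
  # write the generated VAS back into the stored (normalized) feature table
  ft <- as.data.frame(norm$table)
  ft$vas <- ratings$vas[match(ft$rating_id, ratings$rating_id)]
  features <- feature_table(ft, feature_names = feature_names(norm$table))
  for (pid in names(bundles)) {
    r_p <- ratings[ratings$participant_id == pid, , drop = FALSE]
    bundles[[pid]] <- inject_missingness(bundles[[pid]], r_p, schedules[[pid]],
                                         spec$missing_rate,
                                         seed = child_seed(spec$seed, "gaps"))
  }
  cohort <- list(participants = participants, bundles = bundles,
                 schedules = schedules, weather = weather, ratings = ratings,
                 features = features,
                 truth = c(unclass(truth), list(tabulated = tabulate_truth(truth))),
                 spec = spec, config = config)
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants (%s), %d ratings, %d days\n",
              nrow(x$participants),
              paste(table(x$participants$group), collapse = "/"),
              nrow(x$ratings), x$spec$days))
  invisible(x)
}
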