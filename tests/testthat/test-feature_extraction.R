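test_that("Poincare metrics match brute-force formulas on toy beat lists", {
  pm <- poincare_metrics(c(800, 810, 790, 805, 795, 800, 810, 790, 805, 795))
  # population SD of the 10-beat list, computed directly
  x <- c(800, 810, 790, 805, 795, 800, 810, 790, 805, 795)
  expect_equal(pm$sdnn, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(pm$sdnn, sqrt(50), tolerance = 1e-9)

  alt <- rep(c(800, 900), 5)
  pm2 <- poincare_metrics(alt)
  expect_equal(pm2$sd1, 100 / sqrt(2), tolerance = 1e-9)
  expect_equal(pm2$sd2, 0, tolerance = 1e-9)

  pm3 <- poincare_metrics(rep(850, 20))
  expect_equal(c(pm3$sdnn, pm3$sd1, pm3$sd2), c(0, 0, 0))
  expect_error(poincare_metrics(c(800, 810)), "at least 10")
})

test_that("SD1 equals RMSSD/sqrt(2) exactly on random cleaned windows", {
  withr::with_seed(33, {
    err <- vapply(1:1000, function(i) {
      x <- 850 + cumsum(rnorm(30, 0, 20))
      abs(poincare_metrics(x)$sd1 - sqrt(mean(diff(x)^2)) / sqrt(2))
    }, numeric(1))
  })
  expect_lt(max(err), 1e-12)
})

test_that("IBI cleaning interpolates isolated artifacts and rejects heavy windows", {
  base <- rep(800, 30)
  x <- base; x[c(5, 14, 22)] <- 2000
  cl <- clean_ibi_window(x)
  expect_true(cl$ok)
  expect_equal(cl$n_interpolated, 3L)
  expect_equal(cl$ibis[c(5, 14, 22)], rep(800, 3), tolerance = 1e-9)

  x4 <- base; x4[c(5, 10, 15, 20)] <- 2000
  expect_false(clean_ibi_window(x4)$ok)

  clean <- clean_ibi_window(base)
  expect_true(clean$ok)
  expect_identical(clean$ibis, base)
  expect_equal(clean$n_interpolated, 0L)

  expect_false(clean_ibi_window(rep(800, 5))$ok)  # too few beats
})

test_that("aggregate_stats reproduces the closed-form OLS slope and handles degeneracies", {
  st <- aggregate_stats(c(0, 3600, 7200), c(0, 1, 2), c(0, 7300))
  expect_equal(st$slope, 1.0, tolerance = 1e-12)
  expect_equal(st$mean, 1.0)
  expect_equal(st$min, 0)
  expect_equal(st$max, 2)

  one <- aggregate_stats(100, 5, c(0, 200))
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd) && is.na(one$slope))

  withr::with_seed(4, {
    t <- sort(runif(50, 0, 7200)); v <- rnorm(50)
    st2 <- aggregate_stats(t, v, c(0, 7200))
    oracle <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2) * 3600
    expect_equal(st2$slope, oracle, tolerance = 1e-10)
    expect_equal(st2$sd, sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  })
})

test_that("horizons collapse exactly as the wake-clipping rule dictates", {
  sched <- data.frame(night = 0, onset = 23 * 3600 - 86400, wake = 7 * 3600)
  # rating 30 min after waking: all look-back windows equal the awake window
  hz <- build_horizons(7.5 * 3600, sched)
  expect_equal(hz$h1, c(7 * 3600, 7.5 * 3600))
  expect_equal(hz$h3, hz$h1)
  expect_equal(hz$h6, hz$h1)
  expect_equal(hz$aw, hz$h1)
  # rating 2 h after waking: 3 h and 6 h windows equal the awake window
  hz2 <- build_horizons(9 * 3600, sched)
  expect_equal(hz2$h1, c(8 * 3600, 9 * 3600))
  expect_equal(hz2$h3, c(7 * 3600, 9 * 3600))
  expect_equal(hz2$h6, hz2$h3)
  expect_equal(hz2$aw, hz2$h3)
  # rating 7 h after waking: plain window arithmetic
  hz3 <- build_horizons(14 * 3600, sched)
  expect_equal(hz3$h1, c(13 * 3600, 14 * 3600))
  expect_equal(hz3$h3, c(11 * 3600, 14 * 3600))
  expect_equal(hz3$h6, c(8 * 3600, 14 * 3600))
  expect_equal(hz3$aw, c(7 * 3600, 14 * 3600))
  expect_equal(hz3$as, c(sched$onset, sched$wake))
  expect_error(build_horizons(6 * 3600, sched), "precedes the first")
})

test_that("rest windows obey the printed heart-rate threshold formula", {
  b <- known_schedule_bundle()  # age 30: threshold 0.55 * 190 = 104.5 bpm
  cfg <- run_config()
  expect_equal(cfg$rest_hr_fraction * (220 - 30), 104.5)
  win <- detect_rest_windows(b$hr, b$acc, b$ibi, b$age,
                             c(24 * 3600, 30 * 3600), cfg)
  expect_gt(nrow(win), 0)
  expect_true(all(win$mean_hr < 104.5))
  expect_true(all(win$acc_sd < cfg$motion_sd_threshold))
  expect_true(all(win$n_interpolated < cfg$max_artifact_ibis))
  expect_true(all(win$start >= 24 * 3600 & win$end <= 30 * 3600))
  expect_true(all(diff(win$start) >= 300))  # non-overlapping 5-min tiles
  # high heart rate disqualifies a window even without motion
  hr_hi <- b$hr; hr_hi$value <- hr_hi$value + 60
  expect_equal(nrow(detect_rest_windows(hr_hi, b$acc, b$ibi, b$age,
                                        c(24 * 3600, 30 * 3600), cfg)), 0L)
})

test_that("continuous arm motion leaves no rest windows", {
  b <- known_schedule_bundle()
  acc_noisy <- b$acc
  withr::with_seed(2, acc_noisy$value <- abs(rnorm(nrow(acc_noisy), 0.5, 0.3)))
  win <- detect_rest_windows(b$hr, acc_noisy, b$ibi, b$age,
                             c(24 * 3600, 25 * 3600), run_config())
  expect_equal(nrow(win), 0L)
})

test_that("every emitted rest window survives the independent auditor", {
  b <- known_schedule_bundle()
  cfg <- run_config()
  win <- detect_rest_windows(b$hr, b$acc, b$ibi, b$age,
                             c(0, 3 * 86400), cfg)
  expect_gt(nrow(win), 50)
  expect_true(all(audit_rest_windows(win, b, cfg)))
})

test_that("electrodermal peak counting respects the prominence threshold", {
  t <- seq(0, 3599, by = 60)
  flat <- data.frame(time = t, value = rep(2, length(t)))
  expect_equal(count_eda_peaks(flat, c(0, 3600))$count, 0L)
  bumps <- rep(2, length(t))
  at <- round(seq(4, 56, length.out = 7))
  for (j in at) bumps[j:min(j + 2, length(t))] <-
    bumps[j:min(j + 2, length(t))] + c(0.4, 0.25, 0.1)
  df <- data.frame(time = t, value = bumps)
  expect_equal(count_eda_peaks(df, c(0, 3600))$count, 7L)
  small <- data.frame(time = t, value = 2 + (bumps - 2) * 0.05)
  expect_equal(count_eda_peaks(small, c(0, 3600))$count, 0L)
})

test_that("activity features: step prorating and the trapezoidal integral", {
  acc <- data.frame(time = seq(0, 7200 - 60, by = 60), value = 1)
  steps <- data.frame(time = c(0, 60, 120), value = c(10, 0, 25))
  af <- activity_features(acc, steps, c(0, 7200), step_interval = 60)
  expect_equal(af$steps, 35)
  expect_equal(af$int, 2.0, tolerance = 1e-12)  # constant 1.0 over 2 h
  # interval straddling the edge is prorated by overlap
  af2 <- activity_features(acc, data.frame(time = -30, value = 40),
                           c(0, 7200), step_interval = 60)
  expect_equal(af2$steps, 20)
})

test_that("routine features: interval arithmetic and deviations from study means", {
  sched <- data.frame(night = 0:1,
                      onset = c(23, 47) * 3600,
                      wake = c(31, 55) * 3600)  # 23:00-07:00 both nights
  rf <- routine_features(33.5 * 3600, sched)  # 09:30 on day 1
  expect_equal(rf$sleep_duration, 8)
  expect_equal(rf$time_awake, 2.5)
  expect_equal(rf$time_of_day, 9.5)
  expect_equal(rf$wake_dev, 0)  # woke exactly at the study-mean wake time
  expect_equal(rf$bed_dev, 0)
  before <- routine_features(10 * 3600, sched[sched$night > 0, ])
  expect_true(is.na(before$sleep_duration))  # no completed night yet
})

test_that("weather features are day-constant and masked when the day is absent", {
  w <- data.frame(day = 1, temp_mean = 12, temp_min = 7, felttemp_min = 5,
                  dew_mean = 6, humidity_mean = 70)
  a <- weather_features(w, 1 * 86400 + 9 * 3600)
  b <- weather_features(w, 1 * 86400 + 20 * 3600)
  expect_identical(a, b)
  expect_lte(a$temp_day_min, a$temp_day_mean)
  miss <- weather_features(w, 2 * 86400 + 9 * 3600)
  expect_true(all(is.na(unlist(miss))))
})

test_that("sleep/wake estimation recovers a known schedule to the minute scale", {
  b <- known_schedule_bundle()
  sched <- estimate_sleep_wake(b$acc, b$hr)
  # nights 0 and 1 lie fully inside the 3-day recording; the truncated
  # blocks at the edges are not expected to be recovered
  full <- sched[sched$night %in% c(0, 1), ]
  expect_equal(nrow(full), 2L)
  for (i in seq_len(nrow(full))) {
    true_onset <- full$night[i] * 86400 + 23 * 3600
    true_wake <- (full$night[i] + 1) * 86400 + 7 * 3600
    expect_lt(abs(full$onset[i] - true_onset), 15 * 60)
    expect_lt(abs(full$wake[i] - true_wake), 15 * 60)
  }
  expect_error(estimate_sleep_wake(b$acc[b$acc$time < 3600, ],
                                   b$hr[b$hr$time < 3600, ]), "24 h")
})

test_that("constant high activity yields no sleep and the longest quiet period wins", {
  dt <- 60
  t <- seq(0, 2 * 86400 - dt, by = dt)
  withr::with_seed(3, {
    busy <- data.frame(time = t, value = abs(rnorm(length(t), 0.5, 0.2)))
    hr_busy <- data.frame(time = t, value = 90 + rnorm(length(t), 0, 2))
  })
  expect_equal(nrow(estimate_sleep_wake(busy, hr_busy)), 0L)
  # one 8 h and one 40 min quiet period in the same night: the 8 h one is kept
  quiet8 <- (t %% 86400) >= 23 * 3600 | (t %% 86400) < 7 * 3600
  quiet40 <- (t %% 86400) >= 13 * 3600 & (t %% 86400) < 13 * 3600 + 40 * 60
  withr::with_seed(4, {
    acc <- ifelse(quiet8 | quiet40, 0.005, 0.3) + rnorm(length(t), 0, 0.004)
    hr <- ifelse(quiet8 | quiet40, 55, 78) + rnorm(length(t), 0, 1)
  })
  sched <- estimate_sleep_wake(data.frame(time = t, value = abs(acc)),
                               data.frame(time = t, value = hr))
  expect_true(all((sched$wake - sched$onset) > 6 * 3600))
})

test_that("ratings during detected sleep are excluded with a warning", {
  co <- tiny_cohort()
  pid <- names(co$bundles)[1]
  b <- co$bundles[[pid]]
  sch <- co$schedules[[pid]]
  r <- data.frame(rating_id = c("ok1", "bad"),
                  time = c(sch$wake[1] + 3 * 3600, sch$onset[2] + 3600),
                  vas = c(3, 4))
  expect_warning(ft <- assemble_features(b, r, sch, co$weather, co$config),
                 "sleep interval")
  expect_equal(as.data.frame(ft)$rating_id, "ok1")
})

test_that("nested horizons give non-increasing minima and non-decreasing maxima", {
  ft <- do.call(rbind, lapply(tiny_raw_tables(), as.data.frame))
  # identify ratings more than 6 h after waking: h1 within h3 within h6
  sig <- c("hr", "eda", "temp", "acc")
  late <- ft$time_awake > 6.2
  skip_if(sum(late, na.rm = TRUE) == 0)
  for (s in sig) {
    mins <- ft[late, paste0(s, c("_1h_min", "_3h_min", "_6h_min"))]
    maxs <- ft[late, paste0(s, c("_1h_max", "_3h_max", "_6h_max"))]
    ok <- stats::complete.cases(mins) & stats::complete.cases(maxs)
    expect_true(all(mins[ok, 1] >= mins[ok, 2] & mins[ok, 2] >= mins[ok, 3]))
    expect_true(all(maxs[ok, 1] <= maxs[ok, 2] & maxs[ok, 2] <= maxs[ok, 3]))
  }
})

test_that("extraction is deterministic and order-independent across ratings", {
  co <- tiny_cohort()
  pid <- names(co$bundles)[2]
  b <- co$bundles[[pid]]
  r <- co$ratings[co$ratings$participant_id == pid, c("rating_id", "time", "vas")]
  f1 <- assemble_features(b, r, co$schedules[[pid]], co$weather, co$config)
  f2 <- assemble_features(b, r[rev(seq_len(nrow(r))), ], co$schedules[[pid]],
                          co$weather, co$config)
  d1 <- as.data.frame(f1)
  d2 <- as.data.frame(f2)
  d2 <- d2[match(d1$rating_id, d2$rating_id), ]
  rownames(d2) <- NULL
  expect_equal(d1, d2, tolerance = 1e-12)
})
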