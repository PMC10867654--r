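# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Feature-level simulator: participants x ratings with N(0,1) features and a
# response assembled from named effect functions (already normalized scale).
sim_feature_data <- function(n_participants, n_ratings, features,
                             effects = list(), noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_participants), function(p) {
      X <- matrix(stats::rnorm(n_ratings * length(features)),
                  n_ratings, length(features),
                  dimnames = list(NULL, features))
      y <- stats::rnorm(n_ratings, 0, noise_sd)
      for (nm in names(effects)) y <- y + effects[[nm]](X[, nm])
      cbind(data.frame(participant_id = sprintf("p%02d", p),
                       rating_id = sprintf("p%02d_r%03d", p, seq_len(n_ratings)),
                       rating_time = seq_len(n_ratings) * 3600,
                       vas = y, stringsAsFactors = FALSE),
            as.data.frame(X))
    }))
  })
}

# A small raw cohort (4 controls, 5 days) shared by io / extraction tests.
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    generate_cohort(cohort_spec(n_co = 4, n_ms1 = 0, n_ms2 = 0, days = 5,
                                missing_rate = 0.25, seed = 42),
                    config = run_config(seed = 42))
  })
}

# Raw (unnormalized) per-participant feature tables for the tiny cohort,
# extracted from the post-missingness bundles with the true schedules.
tiny_raw_tables <- function() {
  cached("tiny_raw_tables", function() {
    co <- tiny_cohort()
    lapply(names(co$bundles), function(pid) {
      r <- co$ratings[co$ratings$participant_id == pid,
                      c("rating_id", "time", "vas")]
      assemble_features(co$bundles[[pid]], r, co$schedules[[pid]],
                        co$weather, co$config)
    })
  })
}

# End-to-end cohort: two groups with disjoint truth effect sets (controls and
# dysfunctional-ANS patients of the default truth), run through the full
# pipeline: stream generation -> sleep estimation from the data -> feature
# extraction -> per-participant normalization -> zero imputation.
e2e_fixture <- function() {
  cached("e2e", function() {
    cfg <- run_config(seed = 101, k = 8, n_subsamples = 25,
                      n_perturbations = 10)
    spec <- cohort_spec(n_co = 10, n_ms1 = 0, n_ms2 = 10, days = 14,
                        missing_rate = 0.25, noise_sd = 0.8, seed = 101)
    cohort <- generate_cohort(spec, config = cfg)
    tabs <- lapply(names(cohort$bundles), function(pid) {
      b <- cohort$bundles[[pid]]
      sched <- estimate_sleep_wake(b$acc, b$hr)
      r <- cohort$ratings[cohort$ratings$participant_id == pid,
                          c("rating_id", "time", "vas")]
      suppressWarnings(assemble_features(b, r, sched, cohort$weather, cfg))
    })
    ft <- fatiguecast:::bind_feature_tables(tabs)
    norm <- suppressWarnings(normalize_per_participant(ft))
    imp <- impute_zero(norm$table)
    fn <- feature_names(imp$table)
    grp <- function(g) {
      pid <- cohort$participants$id[cohort$participants$group == g]
      keep <- as.data.frame(imp$table)$participant_id %in% pid
      list(table = feature_table(as.data.frame(imp$table)[keep, , drop = FALSE],
                                 feature_names = fn),
           mask = imp$mask[keep, , drop = FALSE])
    }
    list(cohort = cohort, cfg = cfg, table = imp$table, mask = imp$mask,
         co = grp("CO"), ms2 = grp("MS_II"))
  })
}

# One hand-built two-night bundle with a known sleep schedule (quiet + low-HR
# nights 23:00-07:00) for sleep-detection and rest-window tests.
known_schedule_bundle <- function() {
  cached("known_bundle", function() {
    withr::with_seed(9, {
      dt <- 60
      t <- seq(0, 3 * 86400 - dt, by = dt)
      asleep <- (t %% 86400) >= 23 * 3600 | (t %% 86400) < 7 * 3600
      acc <- ifelse(asleep, 0.005, 0.2) + stats::rnorm(length(t), 0, 0.004)
      hr <- ifelse(asleep, 55, 75) + stats::rnorm(length(t), 0, 1)
      mk <- function(v) data.frame(time = t, value = v)
      ibi <- generate_ibi_series(list(mean_ibi = 850, sdnn = 40, sd1 = 28),
                                 3 * 86400, seed = 9)
      sensor_bundle("kb01", 30, mk(hr), mk(2 + 0 * t), mk(33 + 0 * t),
                    mk(abs(acc)), ibi, mk(stats::rpois(length(t), 0.1)))
    })
  })
}
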