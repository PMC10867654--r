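test_that("participant metrics follow the SST-about-zero definition", {
  y <- c(1, -1)
  perfect <- participant_metrics(y, y)
  expect_equal(perfect$r2, 100)
  expect_equal(perfect$mae, 0)
  zero <- participant_metrics(y, c(0, 0))
  expect_equal(zero$r2, 0)
  half <- participant_metrics(y, c(0.5, -0.5))
  expect_equal(half$r2, 75)
  expect_equal(half$mae, 0.5)
  expect_equal(half$rmse, 0.5)
  expect_error(participant_metrics(numeric(0), numeric(0)), "non-empty")
})

test_that("MAE never exceeds RMSE (power-mean inequality)", {
  withr::with_seed(14, {
    for (i in 1:50) {
      n <- sample(2:30, 1)
      m <- participant_metrics(rnorm(n), rnorm(n))
      expect_lte(m$mae, m$rmse + 1e-12)
    }
  })
})

test_that("the baseline regressor scores exactly zero R2 and near-unit RMSE", {
  withr::with_seed(15, {
    df <- data.frame(rating_id = as.character(1:600),
                     participant_id = rep(sprintf("p%d", 1:6), each = 100),
                     rating_time = 1:600, vas = rnorm(600), f1 = rnorm(600))
  })
  ft <- feature_table(df)
  norm <- normalize_per_participant(ft)
  bl <- baseline_evaluate(norm$table)
  expect_true(all(bl$per_participant$complete$r2 == 0))
  expect_equal(unname(bl$means$complete["rmse"]), 1, tolerance = 1e-9)
  # single-rating participant: mae = |y|, r2 = 0
  one <- participant_metrics(0.7, 0)
  expect_equal(one$r2, 0)
  expect_equal(one$mae, 0.7)
})

test_that("paired Wilcoxon matches the exact enumeration oracle", {
  expect_equal(compare_wilcoxon(rep(1, 8), rep(1, 8)), 1.0)
  a <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0)
  expect_equal(compare_wilcoxon(a + 1, a), 2 / 1024, tolerance = 1e-12)
  # brute-force oracle: enumerate all sign assignments of the rank statistic
  wilcox_oracle <- function(a, b) {
    d <- a - b
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    vs <- as.vector(signs %*% r)
    min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
  }
  withr::with_seed(16, {
    for (i in 1:5) {
      a <- rnorm(8); b <- rnorm(8)
      expect_equal(compare_wilcoxon(a, b), wilcox_oracle(a, b),
                   tolerance = 1e-10)
    }
  })
  expect_error(compare_wilcoxon(1:3, 2:4), "at least 5")
})

test_that("LOPO recovers signal and a pure-noise group scores near zero", {
  effects <- list(x1 = function(v) 0.9 * tanh(v), x2 = function(v) 0.6 * v)
  d <- sim_feature_data(8, 40, c("x1", "x2", "x3"), effects, noise_sd = 0.6,
                        seed = 20)
  ft <- feature_table(d, feature_names = c("x1", "x2", "x3"))
  imp <- impute_zero(ft)
  cfg <- run_config(k = 8)
  ev <- lopo_evaluate(imp$table, imp$mask, c("x1", "x2"), cfg)
  bl <- baseline_evaluate(imp$table)
  expect_gt(ev$means$complete["r2"], 20)
  expect_lt(compare_wilcoxon(ev$per_participant$complete$r2,
                             bl$per_participant$complete$r2), 0.05)
  # pure noise: group-mean R2 within 5 points of zero
  dn <- sim_feature_data(8, 40, c("x1", "x2"), noise_sd = 1, seed = 21)
  ftn <- feature_table(dn, feature_names = c("x1", "x2"))
  impn <- impute_zero(ftn)
  evn <- lopo_evaluate(impn$table, impn$mask, c("x1", "x2"), cfg)
  expect_lt(abs(evn$means$complete["r2"]), 5)
})

test_that("across-group evaluation transfers under a shared truth and rejects overlap", {
  effects <- list(x1 = function(v) 0.9 * tanh(v))
  tr <- sim_feature_data(8, 40, c("x1", "x2"), effects, noise_sd = 0.6, seed = 22)
  te <- sim_feature_data(6, 40, c("x1", "x2"), effects, noise_sd = 0.6, seed = 23)
  te$participant_id <- sub("^p", "q", te$participant_id)
  te$rating_id <- sub("^p", "q", te$rating_id)
  ftr <- feature_table(tr, feature_names = c("x1", "x2"))
  fte <- feature_table(te, feature_names = c("x1", "x2"))
  itr <- impute_zero(ftr); ite <- impute_zero(fte)
  cfg <- run_config(k = 8)
  across <- across_group_evaluate(itr$table, itr$mask, ite$table, ite$mask,
                                  "x1", cfg)
  within <- lopo_evaluate(ite$table, ite$mask, "x1", cfg)
  expect_lt(abs(across$means$complete["r2"] - within$means$complete["r2"]), 5)
  expect_error(across_group_evaluate(itr$table, itr$mask, itr$table, itr$mask,
                                     "x1", cfg), "share participants")
  # single-participant test group is a valid boundary case
  one <- ite$table[as.data.frame(ite$table)$participant_id == "q01", ]
  onem <- ite$mask[as.data.frame(ite$table)$participant_id == "q01", , drop = FALSE]
  res1 <- across_group_evaluate(itr$table, itr$mask,
                                feature_table(as.data.frame(one),
                                              feature_names = c("x1", "x2")),
                                onem, "x1", cfg)
  expect_equal(res1$n_participants, 1L)
})

test_that("the ablation grid enumerates 1 + 4 + 4 + 1 configurations", {
  effects <- list(hr_1h_mean = function(v) 0.9 * tanh(v),
                  time_of_day = function(v) 0.7 * v)
  feats <- c("hr_1h_mean", "sdnn_1h_sd", "eda_1h_mean", "acc_1h_max",
             "temp_day_mean", "time_of_day")
  d <- sim_feature_data(8, 30, feats, effects, noise_sd = 0.7, seed = 24)
  ft <- feature_table(d, feature_names = feats)
  imp <- impute_zero(ft)
  cfg <- run_config(k = 6, n_subsamples = 8, n_perturbations = 6)
  abl <- ablation_study(imp$table, imp$mask, feats, cfg, seed = 24)
  expect_equal(nrow(abl), 10L)
  expect_setequal(abl$configuration,
                  c("all", paste0("minus_", c("CAR", "EDA", "ACC", "WEA")),
                    paste0("only_", c("CAR", "EDA", "ACC", "WEA")),
                    "routine_only"))
  # routine features are present in every configuration's candidate set
  sel <- attr(abl, "selections")
  expect_true(all(vapply(abl$configuration, function(nm) {
    any(feature_groups(sel[[nm]]) == "ROUTINE") || length(sel[[nm]]) > 0
  }, logical(1))))
})

test_that("Spearman correlation matches the Pearson-on-ranks oracle", {
  expect_equal(correlate_mean_vas_fsmc(
    data.frame(mean_vas = 1:3, fsmc = c(10, 20, 30)))$rho, 1.0)
  expect_equal(correlate_mean_vas_fsmc(
    data.frame(mean_vas = 1:3, fsmc = c(30, 20, 10)))$rho, -1.0)
  withr::with_seed(17, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  })
  out <- correlate_mean_vas_fsmc(data.frame(mean_vas = x, fsmc = y))
  expect_equal(out$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(correlate_mean_vas_fsmc(data.frame(mean_vas = 1:2,
                                                  fsmc = 1:2)), "at least 3")
})
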