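test_that("the smooth basis exposes the expected penalty ranks", {
  withr::with_seed(1, x <- runif(100))
  bb <- build_smooth_basis(x, k = 10)
  expect_equal(ncol(bb$X), 10)
  expect_equal(qr(bb$S_wiggle)$rank, 8)  # k - 2: constant+linear null space
  expect_equal(qr(bb$S_null)$rank, 2)
  # null-space penalty is positive definite on the wiggliness null space
  ev <- eigen(bb$S_wiggle, symmetric = TRUE)
  U0 <- ev$vectors[, 9:10]
  expect_true(all(eigen(t(U0) %*% bb$S_null %*% U0)$values > 0.99))
  expect_error(build_smooth_basis(rep(1, 50)), "constant")
  expect_warning(build_smooth_basis(rep(1:9, 10), k = 10), "reducing basis")
})

test_that("a noiseless quadratic is reproduced through criterion-tuned penalties", {
  withr::with_seed(2, x <- runif(400))
  y <- x^2
  fit <- fit_gam(data.frame(vas = y, x1 = x), "vas", "x1", run_config())
  expect_lt(sqrt(mean((predict(fit, data.frame(x1 = x)) - y)^2)), 1e-3)
})

test_that("with zero penalties the fit is ordinary least squares on the basis", {
  withr::with_seed(3, {
    d <- data.frame(vas = rnorm(300), x1 = runif(300), x2 = rnorm(300))
  })
  fit <- fit_gam(d, "vas", c("x1", "x2"), run_config(), sp = c(0, 0),
                 select = FALSE)
  X <- model.matrix(fit$gam)
  ols <- qr.coef(qr(X), d$vas)
  expect_lt(max(abs(coef(fit$gam) - ols)), 1e-8)
})

test_that("near-noiseless linear signal is recovered with R2 > 0.99", {
  withr::with_seed(4, {
    x <- rnorm(300)
    d <- data.frame(vas = 2 * x + rnorm(300, 0, 0.01), x1 = x)
  })
  fit <- fit_gam(d, "vas", "x1", run_config())
  yhat <- predict(fit, d)
  expect_gt(1 - sum((d$vas - yhat)^2) / sum((d$vas - mean(d$vas))^2), 0.99)
})

test_that("term EDFs: additivity, the unpenalized limit, and the shrinkage limit", {
  withr::with_seed(5, {
    d <- data.frame(vas = rnorm(300), x1 = runif(300), x2 = rnorm(300))
  })
  fit <- fit_gam(d, "vas", c("x1", "x2"), run_config())
  total <- term_edf(fit, "x1") + term_edf(fit, "x2") + 1
  expect_equal(total, sum(fit$gam$edf), tolerance = 1e-6)
  # zero penalty: EDF = k - 1 (one df absorbed by centering)
  f0 <- fit_gam(d, "vas", "x1", run_config(), sp = 0, select = FALSE)
  expect_equal(term_edf(f0, "x1"), 9, tolerance = 1e-8)
  # infinite penalty: the whole term (null space included) shrinks away
  finf <- fit_gam(d, "vas", "x1", run_config(), sp = 1e10)
  expect_lt(term_edf(finf, "x1"), 1e-3)
  expect_error(term_edf(fit, "nope"), "unknown term")
  expect_error(term_pvalue(fit, "nope"), "unknown term")
})

test_that("term EDF decreases monotonically with the shrinkage penalty weight", {
  withr::with_seed(6, {
    x <- rnorm(400)
    d <- data.frame(vas = sin(x) + rnorm(400, 0, 0.3), x1 = x)
  })
  edfs <- vapply(c(1e-4, 1e-2, 1, 1e2, 1e4, 1e6, 1e8), function(s) {
    term_edf(fit_gam(d, "vas", "x1", run_config(), sp = s), "x1")
  }, numeric(1))
  expect_true(all(diff(edfs) <= 1e-8))
  expect_lt(edfs[length(edfs)], 0.01)
})

test_that("pure-noise terms are shrunk to (near) nothing under REML", {
  cfg <- run_config(method = "REML")
  edfs <- unlist(lapply(1:6, function(s) {
    d <- sim_feature_data(1, 500, paste0("x", 1:5), noise_sd = 1, seed = s)
    fit <- fit_gam(d, "vas", paste0("x", 1:5), cfg)
    vapply(paste0("x", 1:5), term_edf, 0, fit = fit)
  }))
  expect_gt(mean(edfs < 0.5), 0.7)  # most null terms effectively removed
  expect_lt(mean(edfs), 0.5)
})

test_that("a strong smooth effect is significant and its shape is recovered", {
  withr::with_seed(7, {
    x <- runif(500)
    d <- data.frame(vas = sin(2 * pi * x) + rnorm(500, 0, 0.2), x1 = x)
  })
  fit <- fit_gam(d, "vas", "x1", run_config())
  expect_lt(term_pvalue(fit, "x1"), 0.001)
  pe <- partial_effect(fit, "x1", grid = seq(0.02, 0.98, length.out = 60))
  expect_gt(cor(pe$effect, sin(2 * pi * pe$grid)), 0.95)
})

test_that("shape classification labels the canonical curves", {
  expect_identical(classify_shape(c(0, 0.5, 1)), "inc")
  expect_identical(classify_shape(c(1, 0.5, 0)), "dec")
  expect_identical(classify_shape(c(0, 1, 0)), "concave")
  expect_identical(classify_shape(c(0, -1, 0)), "convex")
  expect_identical(classify_shape(rep(0, 5)), "flat")
  expect_identical(classify_shape(c(0, 0.001, 0)), "flat")  # below tolerance
})

test_that("fit_gam guards its preconditions", {
  withr::with_seed(8, d <- data.frame(vas = rnorm(50), x1 = rnorm(50),
                                      x2 = c(NA, rnorm(49))))
  expect_error(fit_gam(d, "vas", c("x1", "x2"), run_config()), "complete data")
  d2 <- d[!is.na(d$x2), ]
  expect_error(fit_gam(d2[1:15, ], "vas", c("x1", "x2"), run_config()),
               "insufficient data")
  expect_error(fit_gam(d2, "vas", "x9", run_config()), "absent")
  d2$const <- 1
  expect_error(fit_gam(d2, "vas", "const", run_config()), "constant")
})

test_that("backward elimination keeps signal, drops noise, and logs a shrinking trace", {
  effects <- list(x1 = function(v) 0.9 * tanh(v),
                  x2 = function(v) -0.9 * tanh(v))
  d <- sim_feature_data(10, 35, paste0("x", 1:5), effects, noise_sd = 0.7,
                        seed = 31)
  cfg <- run_config(n_subsamples = 15, k = 8)
  out <- backward_eliminate(d, paste0("x", 1:5), cfg, seed = 31)
  expect_true(all(c("x1", "x2") %in% out$selected))
  expect_s3_class(out$trace, "elimination_trace")
  # the candidate set never grows across iterations
  sizes <- tapply(out$trace$candidate, out$trace$iteration, length)
  expect_true(all(diff(sizes) <= 0))
  # deterministic under the seed
  out2 <- backward_eliminate(d, paste0("x", 1:5), cfg, seed = 31)
  expect_identical(out$selected, out2$selected)
  expect_equal(out$trace$mean_p, out2$trace$mean_p, tolerance = 1e-12)
})

test_that("a single strongly informative candidate is retained as significant", {
  for (s in 1:3) {
    d <- sim_feature_data(8, 30, "x1",
                          list(x1 = function(v) tanh(v)), noise_sd = 0.5,
                          seed = 100 + s)
    out <- backward_eliminate(d, "x1", run_config(n_subsamples = 10, k = 8),
                              seed = s)
    expect_identical(out$selected, "x1")
    final <- out$trace[out$trace$phase == "full", ]
    expect_lt(final$mean_p[nrow(final)], 0.05)
  }
})

test_that("elimination of an empty candidate list returns an empty selection", {
  d <- sim_feature_data(5, 20, "x1", seed = 1)
  out <- backward_eliminate(d, character(0), run_config(n_subsamples = 5),
                            seed = 1)
  expect_length(out$selected, 0)
})
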