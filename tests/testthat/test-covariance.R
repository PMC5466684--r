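# Empirical covariance estimator and WLS model fitting.

test_that("covariance model evaluation matches the reference parameter values", {
  m <- ref_sep_model()
  expect_equal(eval_separable(m, 0, 0), 1)
  expect_equal(eval_separable(m, 10000, 0), exp(-3))
  expect_equal(eval_separable(m, 0, 2), exp(-3))
  expect_equal(eval_separable(m, 10000, 2), exp(-6))
  p <- proj_cov_model(1, 15000)
  expect_equal(eval_projected(p, 0), 1)
  expect_equal(eval_projected(p, 15000), exp(-3))
  r <- seq(0, 60000, by = 1000)
  expect_true(all(diff(eval_projected(p, r)) < 0))
  expect_error(sep_cov_model(-1, 1, 1))
  expect_error(proj_cov_model(1, 0))
})

test_that("empirical covariance handles the hand-computable cases", {
  # constant residual field -> 0 in every bin
  cst <- data.frame(x_m = runif(15, 0, 2e4), y_m = runif(15, 0, 2e4),
                    year = 2008, residual = 4)
  g <- empirical_covariance(cst)
  expect_true(all(abs(g$cov) < 1e-25))

  # two points, same year, residuals +1/-1: zero-lag bin = variance 1,
  # one distance bin with the single cross pair = -1
  two <- data.frame(x_m = c(0, 3000), y_m = 0, year = 2008,
                    residual = c(1, -1))
  g2 <- empirical_covariance(two)
  expect_equal(nrow(g2), 2L)
  expect_equal(g2$cov[g2$h_mid == 0], 1)       # population variance, 1/n
  expect_equal(g2$n_pairs[g2$h_mid == 0], 2L)  # the two self-pairs
  expect_equal(g2$cov[g2$h_mid > 0], -1)
  expect_equal(g2$n_pairs[g2$h_mid > 0], 1L)

  expect_error(empirical_covariance(two[1, ]), "at least 2")
})

test_that("zero-lag bin equals the population variance of the residuals", {
  set.seed(3)
  rec <- data.frame(x_m = runif(60, 0, 5e4), y_m = runif(60, 0, 5e4),
                    year = sample(2008:2012, 60, TRUE),
                    residual = rnorm(60, sd = 2))
  g <- empirical_covariance(rec)
  v0 <- g$cov[g$h_mid == 0 & g$t_lag == 0]
  expect_equal(v0, mean((rec$residual - mean(rec$residual))^2))
})

test_that("estimator is invariant to record order and respects max ranges", {
  set.seed(9)
  rec <- data.frame(x_m = runif(40, 0, 8e4), y_m = runif(40, 0, 8e4),
                    year = sample(2008:2012, 40, TRUE),
                    residual = rnorm(40))
  g <- empirical_covariance(rec, max_spatial = 30000, max_temporal = 2)
  gp <- empirical_covariance(rec[sample(40), ], max_spatial = 30000,
                             max_temporal = 2)
  expect_equal(as.data.frame(g), as.data.frame(gp))
  expect_true(all(g$h_hi <= 30000))
  expect_true(all(g$t_lag <= 2))
  # projected (purely spatial) grid has no temporal column
  gs <- empirical_covariance(rec, temporal = FALSE)
  expect_null(gs$t_lag)
})

test_that("noiseless grids are recovered by the fitter", {
  m <- sep_cov_model(0.8, 12000, 2.5)
  h <- rep(c(0, seq(2500, 47500, by = 5000)), each = 4)
  tl <- rep(0:3, times = 11)
  g <- make_grid(h, tl, cov = eval_separable(m, h, tl), n_pairs = 50L)
  fit <- fit_cov_model(g, "separable_gaussian_exponential")
  expect_equal(fit$model$c0, m$c0, tolerance = 1e-3)
  expect_equal(fit$model$alpha_s, m$alpha_s, tolerance = 1e-3)
  expect_equal(fit$model$alpha_t, m$alpha_t, tolerance = 1e-3)
  expect_lt(fit$wrss, 1e-8)

  p <- proj_cov_model(1, 15000)
  hp <- c(0, seq(2500, 47500, by = 5000))
  gp <- make_grid(hp, cov = eval_projected(p, hp), n_pairs = 50L)
  fitp <- fit_cov_model(gp, "projected_exponential")
  expect_equal(fitp$model$c, 1, tolerance = 1e-3)
  expect_equal(fitp$model$alpha, 15000, tolerance = 1e-3)
})

test_that("AIC prefers the exponential family on exponential-shaped data", {
  p <- proj_cov_model(1, 15000)
  hp <- c(0, seq(2500, 47500, by = 5000))
  gp <- make_grid(hp, cov = eval_projected(p, hp), n_pairs = 50L)
  f_exp <- fit_cov_model(gp, "projected_exponential")
  f_gau <- fit_cov_model(gp, "separable_gaussian_exponential")  # Gaussian in h
  expect_lt(f_exp$aic, f_gau$aic)
})

test_that("fitted parameters are always positive and bin counts are enforced", {
  set.seed(21)
  rec <- data.frame(x_m = runif(50, 0, 6e4), y_m = runif(50, 0, 6e4),
                    year = sample(2008:2012, 50, TRUE), residual = rnorm(50))
  fit <- fit_cov_model(empirical_covariance(rec), "separable_gaussian_exponential")
  expect_gt(fit$model$c0, 0)
  expect_gt(fit$model$alpha_s, 0)
  expect_gt(fit$model$alpha_t, 0)
  tiny <- make_grid(c(0, 5000), cov = c(1, 0.5))
  expect_error(fit_cov_model(tiny, "projected_exponential"), "bins")
})

test_that("Cauchy-Schwarz holds at the origin on simulated fields (soft)", {
  f <- default_field(0)
  det <- detrend(transform(f$records, log_value = log_transform(incidence)),
                 100000, 2)
  g <- empirical_covariance(det)
  v0 <- g$cov[g$h_mid == 0 & g$t_lag == 0]
  expect_true(all(g$cov <= v0 * 1.10))
})
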