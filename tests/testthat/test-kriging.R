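# Ordinary kriging: solver contract, oracle equivalence, search policy.

test_that("ok_estimate solves degenerate systems correctly", {
  p <- proj_cov_model(1, 15000)
  # single neighbour -> weight 1, estimate = that value
  est <- ok_estimate(matrix(1), eval_projected(p, 4000), z = 3.2, sill = 1)
  expect_equal(est$weights, 1)
  expect_equal(est$value, 3.2)
  # two data equidistant from target and from each other -> weights 0.5/0.5
  d <- eval_projected(p, 8000)
  C <- matrix(c(1, d, d, 1), 2)
  c0 <- rep(eval_projected(p, 5000), 2)
  est2 <- ok_estimate(C, c0, z = c(2, 6), sill = 1)
  expect_equal(est2$weights, c(0.5, 0.5))
  expect_equal(est2$value, 4)
  expect_gte(est2$variance, 0)
})

test_that("neighbourhood kriging equals the brute-force global solve", {
  set.seed(13)
  n <- 18
  coords <- cbind(runif(n, 0, 30000), runif(n, 0, 30000))
  z <- rnorm(n)
  p <- proj_cov_model(0.9, 12000)
  cf_sp <- function(a, b) {
    d <- sqrt(sum((a - b)^2))
    eval_projected(p, d)
  }
  data <- data.frame(s_hat_1 = coords[, 1], s_hat_2 = coords[, 2], residual = z)
  targets <- data.frame(s_hat_1 = c(15000, 2000, 28000),
                        s_hat_2 = c(15000, 25000, 1000))
  cfg <- kriging_config(max_neighbors = n, spatial_radius = 1e6,
                        min_neighbors = 1)
  got <- stp_krige(targets, data, p, cfg)
  for (i in seq_len(nrow(targets))) {
    oracle <- brute_force_ok(as.numeric(targets[i, ]), coords, z, cf_sp)
    expect_equal(got$value[i], oracle$value, tolerance = 1e-8)
    expect_equal(sum(oracle$weights), 1, tolerance = 1e-10)
  }

  # space-time version against the same oracle with the separable covariance
  m <- sep_cov_model(1, 10000, 2)
  years <- sample(2008:2012, n, TRUE)
  cf_st <- function(a, b) {
    eval_separable(m, sqrt(sum((a[1:2] - b[1:2])^2)), abs(a[3] - b[3]))
  }
  st_data <- data.frame(x_m = coords[, 1], y_m = coords[, 2], year = years,
                        residual = z)
  st_targets <- data.frame(x_m = c(15000, 2000), y_m = c(15000, 25000),
                           year = c(2010, 2009))
  cfg_st <- kriging_config(max_neighbors = n, spatial_radius = 1e6,
                           temporal_radius = 100, min_neighbors = 1)
  got_st <- stok_krige(st_targets, st_data, m, cfg_st)
  for (i in seq_len(nrow(st_targets))) {
    oracle <- brute_force_ok(c(st_targets$x_m[i], st_targets$y_m[i], st_targets$year[i]),
                             cbind(coords, years), z, cf_st)
    expect_equal(got_st$value[i], oracle$value, tolerance = 1e-8)
  }
})

test_that("kriging is exact at data points with zero variance", {
  set.seed(17)
  n <- 12
  data <- data.frame(s_hat_1 = runif(n, 0, 2e4), s_hat_2 = runif(n, 0, 2e4),
                     residual = rnorm(n))
  p <- proj_cov_model(1, 15000)
  got <- stp_krige(data.frame(s_hat_1 = data$s_hat_1, s_hat_2 = data$s_hat_2),
                   data, p, kriging_config(spatial_radius = 1e6))
  expect_equal(got$value, data$residual, tolerance = 1e-10)
  expect_equal(got$variance, rep(0, n), tolerance = 1e-10)

  st <- data.frame(x_m = data$s_hat_1, y_m = data$s_hat_2,
                   year = rep(2008:2011, 3), residual = data$residual)
  m <- sep_cov_model(1, 10000, 2)
  got_st <- stok_krige(st[, c("x_m", "y_m", "year")], st, m,
                       kriging_config(spatial_radius = 1e6, temporal_radius = 50))
  expect_equal(got_st$value, st$residual, tolerance = 1e-10)
})

test_that("STOK at a single time slice reduces to spatial OK (separability)", {
  set.seed(19)
  n <- 15
  coords <- cbind(runif(n, 0, 25000), runif(n, 0, 25000))
  z <- rnorm(n)
  m <- sep_cov_model(1, 10000, 2)
  st <- data.frame(x_m = coords[, 1], y_m = coords[, 2], year = 2010,
                   residual = z)
  target <- data.frame(x_m = 12000, y_m = 9000, year = 2010)
  cfg <- kriging_config(max_neighbors = n, spatial_radius = 1e6,
                        min_neighbors = 1)
  got <- stok_krige(target, st, m, cfg)
  # oracle: purely spatial OK with the Gaussian spatial factor (tau = 0)
  oracle <- brute_force_ok(c(12000, 9000), coords, z,
                           function(a, b) eval_separable(m, sqrt(sum((a - b)^2)), 0))
  expect_equal(got$value, oracle$value, tolerance = 1e-8)
})

test_that("estimates are translation invariant", {
  set.seed(23)
  n <- 10
  data <- data.frame(s_hat_1 = runif(n, 0, 2e4), s_hat_2 = runif(n, 0, 2e4),
                     residual = rnorm(n))
  p <- proj_cov_model(1, 15000)
  t1 <- data.frame(s_hat_1 = 9000, s_hat_2 = 11000)
  a <- stp_krige(t1, data, p, kriging_config(spatial_radius = 1e6))
  shifted <- data
  shifted$s_hat_1 <- shifted$s_hat_1 + 123456
  shifted$s_hat_2 <- shifted$s_hat_2 - 654321
  t2 <- data.frame(s_hat_1 = 9000 + 123456, s_hat_2 = 11000 - 654321)
  b <- stp_krige(t2, shifted, p, kriging_config(spatial_radius = 1e6))
  expect_equal(a$value, b$value, tolerance = 1e-10)
})

test_that("search radius expands before failing and duplicates are averaged", {
  p <- proj_cov_model(1, 15000)
  data <- data.frame(s_hat_1 = c(0, 25000, 26000, 27000),
                     s_hat_2 = 0, residual = c(9, 1, 2, 3))
  # target near origin: only 1 datum within 10 km, 4 within 80 km (8x)
  got <- stp_krige(data.frame(s_hat_1 = 1000, s_hat_2 = 0), data, p,
                   kriging_config(spatial_radius = 10000, min_neighbors = 4))
  expect_equal(got$n_neighbors_used, 4L)
  # beyond 8x the radius -> explicit failure
  far <- data.frame(s_hat_1 = c(0, 9e5), s_hat_2 = 0, residual = c(1, 2))
  expect_error(
    stp_krige(data.frame(s_hat_1 = 4e5, s_hat_2 = 0), far, p,
              kriging_config(spatial_radius = 1000, min_neighbors = 2)),
    "radius expansions")
  # exact duplicate data are averaged, and a coincident target returns it
  dup <- data.frame(s_hat_1 = c(0, 0, 5000), s_hat_2 = 0,
                    residual = c(2, 4, 7))
  gd <- stp_krige(data.frame(s_hat_1 = 0, s_hat_2 = 0), dup, p,
                  kriging_config(spatial_radius = 1e5, min_neighbors = 1))
  expect_equal(gd$value, 3)
  expect_equal(gd$variance, 0)
})

test_that("kriging weights always sum to one", {
  set.seed(29)
  p <- proj_cov_model(1, 8000)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    C <- eval_projected(p, as.matrix(dist(cbind(runif(n, 0, 3e4), runif(n, 0, 3e4)))))
    diag(C) <- 1
    c0 <- eval_projected(p, runif(n, 0, 3e4))
    est <- ok_estimate(C, c0, rnorm(n), sill = 1)
    expect_equal(sum(est$weights), 1, tolerance = 1e-10)
    expect_gte(est$variance, 0)
  }
})
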