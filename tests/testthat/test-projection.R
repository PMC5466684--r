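# Velocity quadratic, projected lags, coordinate transform.

quad_residual <- function(v, h, tau, m) {
  m$alpha_t * tau * v^2 - 2 * m$alpha_t * h * v - m$alpha_s^2
}

test_that("solve_velocity matches closed forms and an independent root oracle", {
  m <- ref_sep_model()
  expect_equal(solve_velocity(0, 2, m), -5000)
  expect_equal(solve_velocity(10000, 2, m), 5000 - 5000 * sqrt(2))
  expect_equal(projected_lag(10000, 2, m), 10000 * sqrt(2))
  expect_equal(projected_lag(0, 2, m), 10000)       # alpha_s * sqrt(tau/alpha_t)
  expect_equal(projected_lag(10000, 0, m), 10000)   # reduces to |h| at tau = 0

  # oracle: the root of the quadratic alpha_t*tau*v^2 - 2*alpha_t*|h|*v -
  # alpha_s^2 via polyroot, picking the one with positive projected lag
  for (case in list(c(0, 2), c(10000, 2), c(25000, 1), c(3000, 4.5))) {
    h <- case[1]; tau <- case[2]
    roots <- Re(polyroot(c(-m$alpha_s^2, -2 * m$alpha_t * h, m$alpha_t * tau)))
    admissible <- roots[h - roots * tau > 0]
    expect_length(admissible, 1L)
    expect_equal(solve_velocity(h, tau, m), admissible, tolerance = 1e-12)
  }
  expect_error(solve_velocity(1000, 0, m), "singular")
})

test_that("velocity root and projected-lag identities hold over a random sweep", {
  set.seed(7)
  n <- 10000
  h <- runif(n, 0, 50000)
  tau <- runif(n, 1e-3, 5)
  as_ <- runif(n, 1000, 50000)
  at_ <- runif(n, 0.5, 5)
  v <- h / tau - (as_ / tau) * sqrt(h^2 / as_^2 + tau / at_)
  res <- abs(at_ * tau * v^2 - 2 * at_ * h * v - as_^2) / as_^2
  expect_lt(max(res), 1e-9)
  r_hat <- as_ * sqrt(h^2 / as_^2 + tau / at_)
  expect_true(all(r_hat > 0))
  expect_lt(max(abs((h - v * tau) - r_hat) / r_hat), 1e-9)
})

test_that("velocity_surface satisfies the quadratic and is increasing in |h|", {
  m <- ref_sep_model()
  surf <- velocity_surface(m, h_grid = seq(0, 50000, by = 2500), tau_grid = 1:5)
  expect_equal(surf$speed_m_per_yr[surf$h_m == 0 & surf$tau_yr == 2], -5000)
  res <- abs(quad_residual(surf$speed_m_per_yr, surf$h_m, surf$tau_yr, m)) / m$alpha_s^2
  expect_lt(max(res), 1e-9)
  for (tau in unique(surf$tau_yr)) {
    sp <- surf$speed_m_per_yr[surf$tau_yr == tau][order(surf$h_m[surf$tau_yr == tau])]
    expect_true(all(diff(sp) > 0))
  }
  expect_error(velocity_surface(m, tau_grid = 0:2))
})

test_that("representative_velocity strategies behave as defined", {
  m <- ref_sep_model()
  g1 <- make_grid(h_mid = 0, t_lag = 2, cov = 0.5, n_pairs = 10L)
  for (strat in c("origin_mean", "paircount_mean", "median")) {
    v <- representative_velocity(g1, m, strat)
    expect_equal(v$speed, -5000)
    expect_identical(v$strategy, strat)
  }
  # equal counts over two bins -> arithmetic mean of the two cell speeds
  g2 <- make_grid(h_mid = c(0, 10000), t_lag = c(2, 2), cov = c(0.5, 0.2),
                  n_pairs = 7L)
  v2 <- representative_velocity(g2, m, "paircount_mean")
  expect_equal(v2$speed, mean(solve_velocity(c(0, 10000), 2, m)))
  # origin_mean uses only the minimum-|h| bins
  expect_equal(representative_velocity(g2, m, "origin_mean")$speed, -5000)
  # fixed:<value> ignores the grid
  expect_equal(representative_velocity(g2, m, "fixed:0")$speed, 0)
  expect_equal(representative_velocity(g2, m, "fixed:-1234.5")$speed, -1234.5)
  # tau = 0 bins are excluded; a grid with only tau = 0 fails
  g0 <- make_grid(h_mid = c(0, 5000), t_lag = c(0, 0), cov = c(1, 0.5))
  expect_error(representative_velocity(g0, m), "tau > 0")
})

test_that("project_coordinates is the printed transform and inverts exactly", {
  pts <- data.frame(x_m = 10000, y_m = 20000, year = 2010)
  out <- project_coordinates(pts, 5000, t0 = 2008, mode = "literal")
  expect_equal(out$s_hat_1, 0)
  expect_equal(out$s_hat_2, 10000)

  # v = 0 -> identity
  id <- project_coordinates(pts, 0, t0 = 2008)
  expect_equal(id$s_hat_1, pts$x_m)
  expect_equal(id$s_hat_2, pts$y_m)

  # roundtrip on a batch, both modes
  set.seed(11)
  batch <- data.frame(x_m = runif(50, 0, 1e5), y_m = runif(50, 0, 1e5),
                      year = sample(2008:2012, 50, TRUE))
  for (mode in c("literal", "vector")) {
    p <- project_coordinates(batch, -3536, t0 = 2008, mode = mode)
    b <- backproject_coordinates(p[, c("s_hat_1", "s_hat_2", "year")],
                                 -3536, t0 = 2008, mode = mode)
    expect_equal(b$x_m, batch$x_m, tolerance = 1e-12)
    expect_equal(b$y_m, batch$y_m, tolerance = 1e-12)
  }
  expect_error(project_coordinates(batch, -3536, t0 = 2008, mode = "vector",
                                   direction = c(1, 1)), "unit")
})

test_that("backtransform_estimates is pure relabeling", {
  targets <- data.frame(x_m = c(1, 2, 3), y_m = c(4, 5, 6), year = 2008:2010)
  est <- data.frame(value = c(10, 20, 30))
  out <- backtransform_estimates(targets, est)
  expect_equal(out$value, c(10, 20, 30))
  perm <- c(3, 1, 2)
  out_perm <- backtransform_estimates(targets[perm, ], est[perm, , drop = FALSE])
  expect_equal(out_perm$value[order(out_perm$year)], c(10, 20, 30))
  expect_error(backtransform_estimates(targets, est[1:2, , drop = FALSE]),
               "row-aligned")
})
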