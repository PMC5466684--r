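# Shared fixtures. Heavy simulations are memoised so the synthetic-data unit
# tests and the acceptance experiments reuse the same fields.

.field_cache <- new.env(parent = emptyenv())

# Default stated-world field (200 locations x 5 years, exponential 15 km,
# speed -5000 m/yr); seeds 0..19 are the experiment seeds.
default_field <- function(seed) {
  key <- paste0("d", seed)
  if (is.null(.field_cache[[key]])) {
    .field_cache[[key]] <- simulate_traveling_field(sim_config(seed = seed))
  }
  .field_cache[[key]]
}

# Same world with zero travel speed.
static_field <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.field_cache[[key]])) {
    .field_cache[[key]] <- simulate_traveling_field(
      sim_config(seed = seed, velocity_speed = 0))
  }
  .field_cache[[key]]
}

# Small, fast field for plumbing tests: 40 locations x 3 years on a 60 km
# square (keeps spatial density comparable to the default world).
small_field <- function(seed = 42, ...) {
  simulate_traveling_field(sim_config(
    n_locations = 40L, years = 2008:2010,
    extent = c(xmin = 0, xmax = 60000, ymin = 0, ymax = 60000),
    seed = seed, ...))
}

# The printed reference separable model (c0 = 1, alpha_s = 10 km,
# alpha_t = 2 yr).
ref_sep_model <- function() sep_cov_model(1, 10000, 2)

# Build a lag_bin_grid by hand (for noiseless fitting tests).
make_grid <- function(h_mid, t_lag = NULL, cov, n_pairs = 1L,
                      bin_width = 5000) {
  g <- data.frame(h_lo = pmax(h_mid - bin_width / 2, 0),
                  h_hi = h_mid + bin_width / 2,
                  h_mid = h_mid)
  if (!is.null(t_lag)) g$t_lag <- t_lag
  g$cov <- cov
  g$n_pairs <- as.integer(rep_len(n_pairs, nrow(g)))
  structure(g, class = c("lag_bin_grid", "data.frame"),
            temporal = !is.null(t_lag))
}

# Independent brute-force ordinary-kriging oracle: full augmented system over
# ALL data, solved with a plain linear solve written independently of the
# package internals.
brute_force_ok <- function(target, coords, z, cov_fun) {
  n <- nrow(coords)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- cov_fun(coords[i, ], coords[j, ])
    }
  }
  c0 <- vapply(seq_len(n), function(i) cov_fun(coords[i, ], target), 0.0)
  A <- cbind(rbind(C, 1), c(rep(1, n), 0))
  sol <- solve(A, c(c0, 1))
  list(value = sum(sol[1:n] * z), weights = sol[1:n], mu = sol[n + 1])
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
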