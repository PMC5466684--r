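# stproj — space-time projection kriging for disease incidence mapping

`stproj` estimates and maps point-referenced, yearly disease incidence (rates
per 100,000) with the **space-time projection (STP)** technique, alongside a
reference **spatiotemporal ordinary kriging (STOK)** implementation. It is
aimed at spatial epidemiologists working with small-area registry panels:
a few hundred locations (e.g. township centroids) observed over a handful of
yearly slices.

## The method

Incidence on the log scale, `y = log(BC + 1)`, is modelled as a *traveling
(frozen) random field*: the spatial pattern is advected rigidly at a spread
velocity `v`, so

    y(s, t) = y(s - v t, 0).

Instead of kriging in the awkward `R^2 x T` domain, STP "compresses" time
into space:

1. Detrend the log incidence with a moving-window mean (100 km spatial,
   2 yr temporal radius) and estimate the empirical space-time covariance of
   the residuals (lags up to 50 km and 5 yr).
2. Fit the multiplicative separable model
   `c(h, tau) = c0 exp(-3|h|^2/alpha_s^2 - 3 tau/alpha_t)` by pair-count
   weighted least squares with AIC model selection.
3. Solve the velocity quadratic
   `alpha_t tau v^2 - 2 alpha_t |h| v - alpha_s^2 = 0` for the admissible
   root (the one keeping the projected lag `r_hat = |h| - v tau` positive)
   and collapse the `v(|h|, tau)` surface to one representative speed.
4. Project every record to `s_hat = s - v t`, re-detrend spatially, and fit
   the exponential covariance `c(r_hat) = c exp(-3 r_hat / alpha)`.
5. Ordinary kriging in the projected plane (N = 50 neighbours, 10 km search
   range), then relabel the estimates back onto `(s, t)` and invert the log
   transform.

STOK kriges the same residuals directly in `R^2 x T` with the separable
covariance (N = 50, 10 km, 2 yr). Both pipelines share indirect age
standardization, 10-fold cross-validation and ME/MAE/RMSE summaries, and a
seeded traveling-random-field simulator that makes every stage verifiable
without access to registry data.

## Worked example

```r
library(stproj)

# a traveling field: 200 townships x 5 years, exponential covariance with a
# 15 km range, spread speed -5000 m/yr along the SW-NE diagonal
field <- simulate_traveling_field(sim_config(seed = 3))
fit <- stp_fit(field$records)
fit$spacetime$fit
#> Covariance fit (separable_gaussian_exponential): AIC = 101.26, WRSS = 310.9 over 55 bins
#> Separable space-time covariance: c0 = 0.7693, alpha_s = 1.477e+04 m, alpha_t = 4.852 yr
fit$projected$velocity
#> Spread velocity: -5214.59 m/yr (strategy = origin_mean, mode = literal)
fit$projected$fit
#> Covariance fit (projected_exponential): AIC = 29.06, WRSS = 107.3 over 11 bins
#> Projected exponential covariance: c = 0.8973, alpha = 1.425e+04 m

compare_stp_stok(field$records, k = 10, seed = 3)
#> STP : ME = -10.4248, MAE = 29.5385, RMSE = 53.4899 (n = 1000), per 100,000
#> STOK: ME = 16.1436, MAE = 55.4929, RMSE = 220.2592 (n = 1000), per 100,000
```

The separable fit recovers the latent spatial scale (`alpha_s` ~ 15 km); the
origin-anchored velocity collapse recovers the generating travel speed
(-5215 vs -5000 m/yr); the projected-domain exponential range (14.3 km)
matches the generating 15 km; and 10-fold cross-validation on the incidence
scale shows the qualitative ordering the method is built around: STP error
well below STOK error on a strongly traveling field.

Command-line interface (same pipelines, CSV in/out):

```sh
Rscript -e 'quit(status = stproj::stp_cli())' simulate --seed 0 --out sim/
Rscript -e 'quit(status = stproj::stp_cli())' crossvalidate \
    --input sim/incidence.csv --method both --k 10 --seed 1 --out cv/
```

## Vignette

See `vignettes/stp-methods.Rmd` for the model, its assumptions, every
tunable parameter with units and defaults, what the simulator does and does
not emulate, and the numerical design choices.
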