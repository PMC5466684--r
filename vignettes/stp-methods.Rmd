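---
title: "Space-time projection kriging: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time projection kriging: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stproj)
```

## The problem and the model

Small-area disease registries report yearly incidence (cases per 100,000,
often age-standardized) at a few hundred administrative centroids. Mapping
these data in continuous space-time with spatiotemporal ordinary kriging
(STOK) requires a space-time covariance model and, implicitly, a composite
space-time metric — both notoriously awkward because a metre and a year are
incommensurable.

The space-time projection (STP) technique sidesteps this by assuming the
incidence field, on the `log(BC + 1)` scale and after removal of a smooth
trend, is a *traveling (frozen) random field*:

$$ y(\mathbf{s}, t) = y(\mathbf{s} - \boldsymbol{\upsilon} t, 0), $$

i.e. one spatial pattern advected rigidly at velocity $\boldsymbol\upsilon$.
Under this assumption the covariance satisfies
$c(\mathbf{h}, \tau) = c(r - \upsilon\tau, 0)$, so estimation can be done by
ordinary spatial kriging in the projected plane
$\hat{\mathbf s} = \mathbf s - \boldsymbol\upsilon t$, and the estimates
relabelled back to $(\mathbf s, t)$ — a pure coordinate transform, with no
interpolation in the back-step.

The velocity is not observed. It is derived from the fitted separable
space-time covariance (Gaussian in space, exponential in time),

$$ c(\mathbf h, \tau) = c_0
   e^{-3 |\mathbf h|^2 / \alpha_s^2 - 3\tau/\alpha_t}, $$

by equating it with its traveling form, which yields the quadratic
$\alpha_t \tau \upsilon^2 - 2 \alpha_t |\mathbf h| \upsilon - \alpha_s^2 = 0$
whose admissible root (the one keeping the projected lag
$\hat r = |\mathbf h| - \upsilon\tau$ positive) is

$$ \upsilon = \frac{|\mathbf h|}{\tau} - \frac{\alpha_s}{\tau}
   \sqrt{|\mathbf h|^2/\alpha_s^2 + \tau/\alpha_t}. $$

This root is strictly negative and lag-dependent; its magnitude measures the
strength of composite space-time correlation along the lag direction.

## Key assumptions

* **Frozen travel.** The spatial pattern changes only by rigid advection over
  the study period. Real incidence surfaces are at best approximately frozen;
  the more the pattern deforms, the less the projection gains.
* **Gaussianity after `log(x+1)`.** Registries contain exact zeros and
  left-skewed rates; `log(BC+1)` brings them near-Gaussian. Estimates are
  back-transformed with `exp(y) - 1`, clamped at zero. No lognormal bias
  correction is applied (the reference analysis uses none); kriging is
  therefore approximately median-unbiased rather than mean-unbiased on the
  rate scale.
* **Second-order stationarity of the residuals** after moving-window
  detrending.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| detrend spatial radius | 100,000 | m | moving-window mean trend |
| detrend temporal radius | 2 (space-time) / disabled (projected) | yr | idem |
| empirical covariance max lags | 50,000 m, 5 yr | | bins beyond are discarded |
| spatial bin width | 5,000 | m | 10 bins to 50 km; data are yearly so temporal bins are integer lags |
| `c0, alpha_s, alpha_t` | fitted | –, m, yr | separable model (practical ranges: decay to $e^{-3}$) |
| `c, alpha` | fitted | –, m | projected exponential model |
| kriging `N` | 50 | | neighbours per target |
| kriging search radii | 10,000 m; 2 yr (STOK) | | doubled up to 3 times if < 3 usable neighbours |
| CV folds `k` | 10 | | random, seeded, equal sizes |

All defaults equal the reference analysis settings; every run writes its
resolved configuration (`run_config.json`) next to its outputs.

## Design choices made where the design was open

**Trend estimator.** "Detrended with a radius" fixes only the window; we use
the unweighted moving-window mean including the centre record. It is the
simplest estimator consistent with a stated radius, and it reconstructs
exactly (`trend + residual = log_value`).

**Fitting and AIC.** The covariance (not the variogram) is fitted, by
pair-count-weighted least squares over non-empty bins, with the
least-squares AIC $n\ln(\mathrm{WRSS}/n) + 2k$ over $n$ non-empty bins. The
optimizer is a deterministic 17-point log-spaced grid per parameter followed
by Nelder-Mead with convergence-checked restarts — no randomness, so fits
are exactly reproducible.

**Time-stable model variant.** The separable family is fitted twice: with
$\alpha_t$ free ($k=3$) and with the temporal factor pinned at 1
($\alpha_t = \infty$, $k=2$); the AIC winner is kept. This matters because
the velocity root is strictly negative for any *finite* $\alpha_t$: on a
field with no real temporal decay, a noise-fitted finite $\alpha_t$ would
manufacture a spurious velocity of up to ~1.5 km/yr and misplace the
projection. With $\alpha_t = \infty$ the root is exactly zero and the
projection degenerates to the identity, which is the correct behaviour for a
time-stable field. In simulation, AIC selects the stable variant on 5/5
static fields and the free variant on 20/20 traveling fields.

**Collapsing the velocity surface.** The solver gives one speed per
$(|\mathbf h|, \tau)$ lag pair; the transform needs one number, and how the
original analysis collapsed the surface is not stated. The default here,
`origin_mean`, averages the root over the bins at the smallest observed
spatial lag (for panel data, co-located pairs across years), weighted by
pair counts. Rationale: under frozen travel the decay of $c(0, \tau)$ is
purely advective, so inverting the temporal margin at the origin is the
classic Taylor-hypothesis velocity estimate. The plausible alternative — a
pair-count-weighted mean over *all* bins — is kept as `paircount_mean` but
is not the default: the speed surface decays like $1/|\mathbf h|$ while
pair counts grow with $|\mathbf h|$, so the all-bin average is pulled toward
zero (measured: about −950 m/yr on fields generated with an effective
literal-mode speed near −3500 m/yr, versus about −5000 m/yr for
`origin_mean`, which recovers the generating travel well enough to bring the
projected-range recovery inside its ±30% target). `median` and
`fixed:<value>` are also available, and the strategy used is recorded in all
outputs.

**Projection mode.** The printed transform subtracts the *scalar* $\upsilon
t$ from each coordinate — a fixed diagonal displacement — although the prose
ties the direction to the pairwise lag vector, which is ill-defined at a
single point. `literal` mode (default) follows the printed transform;
`vector` mode displaces along an explicit unit direction. Both are affine
and exactly invertible; the mode is recorded in the outputs.

**Neighbour ranking in STOK.** Eligible data satisfy
$|\mathbf h| \le \varepsilon_s$, $|\tau| \le \varepsilon_t$; the $N$ with
the highest *covariance* to the target are used. Ranking by covariance
avoids inventing precisely the composite space-time distance the method is
designed to avoid; in the purely spatial case it coincides with distance
ranking. Ties break on stable record order.

**Degenerate inputs.** Exact duplicate data points are averaged before the
solve; a target coinciding with a datum returns that value with zero
variance (exact interpolation, zero-nugget models); singular systems are
retried once with a $10^{-10}\cdot$sill diagonal jitter and then fail naming
the offending records; negative kriging variances are clamped at zero.

## The synthetic world

Without a deposited registry, verification rests on a simulator that
emulates the stated data conditions: 200 township-like locations (minimum
separation 500 m) on a ~130 km square (the study region's area), five
yearly slices, a zero-mean Gaussian latent field drawn *exactly* (dense
symmetric matrix square root) on the projected coordinates so the frozen
identity holds bit-exactly, a planar SW→NE trend (amplitude 1 log-unit), a
baseline mean of 3 log-units, unit sill, exponential covariance with 15 km
practical range, and back-transform `exp(y)-1` clamped at zero (which
produces zero-incidence records, as in real registries). The default travel
speed is −5000 m/yr along the SW→NE diagonal: the magnitude equals the
velocity the solver returns at lag $(0, 2\,\mathrm{yr})$ under the reference
covariance parameters, and the admissible root is always negative, so a
negative default keeps the literal projection geometrically able to align
with the travel. The marginal variance of the real log-incidence field is
never printed (the fitted models have unit sill); the simulator exposes the
sill as a free parameter rather than assuming anything.

What the simulator does **not** emulate: Poisson sampling noise in case
counts, administrative boundary geometry, population pyramids, non-frozen
pattern deformation, and spatially varying velocity. A green test therefore
establishes that the pipeline recovers what it assumes — not that real
incidence fields are frozen.

Within that world, the test suite verifies (seeds fixed, 20 replicates):
the latent variance matches the sill within 25%; the empirical covariance
at projected lags tracks the generating model; the projected-domain
exponential range is recovered within ±30% (median); the projected range
exceeds the space-time model's spatial range on ≥ 15/20 seeds; STP's 10-fold
CV RMSE is ≤ STOK's on ≥ 15/20 strongly traveling fields; and on static
fields the two methods tie at the scale of the data. On the lengthening
comparison: the un-projected comparator is the *space-time model's* spatial
range $\alpha_s$, matching the original analysis, which reports the
projected range as about twice the range of $c(\mathbf h, \tau)$. Fitting an
exponential to raw coordinates pooling all years
(`fit_naive_spatial_model`) is *not* a usable comparator in a frozen world:
pooling smears the covariance into a flatter, lower-sill curve whose
WLS-fitted range is systematically longer, so that comparison inverts for
reasons unrelated to the phenomenon.

## Known limitations

* A single global velocity: strongly anisotropic or spatially varying
  spread violates the transform.
* The velocity surface collapse is a documented stand-in; different
  strategies give different (all negative) speeds.
* Indirect standardization only; no direct (reference-weights) method.
* Coordinates must already be planar metres; no CRS handling.
* The ±30% and 15/20 figures above are properties of the stated synthetic
  world, computed by the test suite — nothing here restates results the
  tests do not themselves compute.
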