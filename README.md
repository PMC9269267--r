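# mbegrowth

Sigmoid growth curves from the Brière family of rate equations: model
fitting, model comparison and leaf-shape applications, in base R.

## The problem

Ontogenetic growth — crop dry mass accumulating over a season, a bamboo
shoot extending after emergence — typically follows an S-shaped curve: slow
at first, fastest somewhere past the middle of the growth period, then
flattening to an asymptote. Symmetric sigmoids such as the logistic force
the growth-*rate* curve to be a symmetric bell, which real data often
contradict: biological rate curves are usually skewed, with a long slow
rise and an abrupt stop.

The Brière equation (BE), best known as a temperature–development-rate
model in thermal biology, produces exactly such skewed bells. Read on the
time axis it gives the growth rate

```
f(x) = a x (x − x_min) (x_max − x)^(1/m),      x ∈ [x_min, x_max],
f(x) = 0 otherwise,
```

where `x_min` and `x_max` are the start and end times of growth, `a` is a
scale constant and `m` a shape exponent. Its modified form (MBE) raises the
whole bracket to an extra elasticity exponent `δ`:

```
f(x) = a | x (x − x_min) (x_max − x)^(1/m) |^δ,
```

which reduces exactly to the BE at `δ = 1`. The extra parameter reshapes
the curvature of the rate curve — and of its integral, the sigmoid growth
curve `y(x) = ∫ f(t) dt` — without moving the support, and it lets the
start of growth be *fixed at the known sowing or emergence time* instead of
being absorbed as a fudge parameter.

This package is for plant scientists and modellers who want to:

* fit both sigmoid growth equations to time–size trajectories by
  Nelder–Mead least squares (start time fixed or free),
* decide whether the extra parameter earns its keep via the RMSE-based
  absolute percentage error (APE) rule — the MBE is preferred only when
  `APE = |RMSE_BE − RMSE_MBE| / RMSE_BE × 100% > 5%` *and* the MBE's RMSE
  is lower,
* read off biological diagnostics: the asymptotic size, the time of
  maximum growth rate (for `x_min = 0` it is `2 m x_max / (2m + 1)`), and
  whether the rate curve is left- or right-skewed,
* fit the same skewed bell as a half-width profile to the boundary
  coordinates of ovate leaves, one curve per margin,
* simulate all of the above with known ground truth.

## Worked example

Simulate a crop-season dataset (15 sampling dates every 5 days from day 14
to 84, 20 replicate plants per date, additive measurement noise at 2% of
the asymptote), fit both models with the start time fixed at sowing, and
compare:

```r
library(mbegrowth)

d <- design_crops_like(seed = 42)
s <- simulate_growth_series(d, label = "crop season")
res <- compare_growth(s, fix_x_min = 0, seed = 1)
print(res$comparison)
#> Model comparison for 'crop season' (n = 300)
#>   RMSE (BE)  = 3.292
#>   RMSE (MBE) = 2.731
#>   APE = 17.03%
#>   preferred model: MBE (extra parameter justified at the 5% rule)

summary(res$fit_mbe)
#> MBE sigmoid growth fit to 'crop season'
#> Growth-model parameters [MBE]
#>   a = 1.88276e-05, m = 4.42203, x_min = 0, x_max = 85.3755, delta = 1.33467
#>   n = 300, RSS = 2238.22, RMSE = 2.73143
#>   asymptotic size = 138.254
#>   maximum growth rate at t = 76.7027 (left-skewed rate curve)
#>   restarts used = 27, seed = 1
```

The generating curve ended growth at day 90 with `δ = 1.4`; the fit
recovers the end time within a few percent even though it lies beyond the
last sampling date, estimates a plateau of ~138 mass units, and places the
fastest growth at day 77 — in the right half of the growth period, i.e. a
left-skewed rate curve, as is typical for crops. The APE of 17% (vs the
BE's higher RMSE) says the extra elasticity parameter is worth carrying
for these data.

Leaf outlines work the same way, with the MBE as a half-width profile per
margin:

```r
up  <- growth_params(0.003, 3,   0, 10, delta = 1.5)
lo  <- growth_params(0.022, 2.2, 0, 10, delta = 1.1)
out <- simulate_leaf_outline(up, lo, n_points = 120)
fit_leaf(register_leaf(out))
```

A thin command-line wrapper (installed at
`system.file("scripts", "mbe-cli", package = "mbegrowth")`) exposes the
same workflow as `simulate | fit | compare | leaffit | curve` subcommands
writing JSON reports; see `?cli_main`.

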