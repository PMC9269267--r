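---
title: "Modelling sigmoid growth with Brière-family rate equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sigmoid growth with Brière-family rate equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbegrowth)
```

## The rate models

Growth of an individual plant (biomass, height) over its growth period is
modelled through its *rate*. The Brière equation (BE), long used for
temperature-dependent development rates of arthropods, doubles as a
time-dependent growth-rate model:

$$f(x) = a\,x\,(x - x_{\min})\,(x_{\max}-x)^{1/m},
  \qquad x \in [x_{\min}, x_{\max}],$$

and $f(x)=0$ outside that support. The modified form (MBE) raises the
bracket, in absolute value, to an elasticity exponent $\delta$:

$$f(x) = a\,\bigl|x\,(x - x_{\min})\,(x_{\max}-x)^{1/m}\bigr|^{\delta}.$$

At $\delta = 1$ the MBE *is* the BE — the reduction is exact, not
asymptotic, and the package's tests assert it to machine precision. The
absolute value is retained for numerical safety only: the support clamp
takes precedence, so regions where the bracket would be negative never
contribute.

Parameters, units, and defaults:

* `a` (> 0): scale constant carrying the size units. It is the only
  parameter affected by proportional rescaling of the size measurements
  (e.g. fresh vs dry mass).
* `m` (> 0, dimensionless): controls how abruptly the rate falls at the
  end of growth, through $(x_{\max}-x)^{1/m}$. Large `m` means an abrupt
  stop.
* `x_min`, `x_max` (time units): start and end of growth. These have
  direct biological meaning (sowing/emergence and maturity), which is why
  the fitting interface lets `x_min` be *fixed* at its known value.
* `delta` (> 0, dimensionless): curve-shape elasticity, with no direct
  biological meaning; it exists to let the sigmoid's curvature match data.
  We place no upper bound on `delta` (or `m`): the optimizer works on the
  log scale, and nothing in the model requires one.

Two closed-form diagnostics come with the family. The rate peaks at the
interior root of
$(2m+1)x^2 - [(1+m)x_{\min} + 2m\,x_{\max}]x + m\,x_{\min}x_{\max} = 0$,
which for $x_{\min}=0$ is $2m\,x_{\max}/(2m+1)$ — always in the *right*
half of the support. Because the MBE is a positive monotone transform of
the BE bracket, the peak location is independent of $\delta$. We classify
a rate curve whose peak lies right of the support midpoint as
*left-skewed* (long left tail), following the usage in thermal biology;
the symmetry tolerance is $10^{-9}(x_{\max}-x_{\min})$.

```{r diagnostics}
p <- growth_params(a = 0.01, m = 3, x_min = 0, x_max = 35)
peak_growth_time(p)
skew_direction(p)
```

## From rate to sigmoid: numerical integration

The cumulative curve $y(x) = \int_{x_{\min}}^{x} f(t)\,dt$ (zero below
$x_{\min}$, a plateau above $x_{\max}$) has no convenient closed form for
general $\delta$, so both models run through the same numeric engine; this
also removes any risk of comparing an analytic BE implementation against a
numeric MBE one. For $x_{\min}=0,\ \delta=1$ the total integral has the
Beta-function closed form $a\,x_{\max}^{3+1/m}B(3, 1+1/m)$, which serves as
an independent oracle in the tests (agreement to $\le 10^{-8}$ relative,
typically $10^{-13}$).

Numerical choices:

* The user-facing `growth_cumulative()` uses adaptive quadrature
  (`stats::integrate`) panel-wise between consecutive requested times,
  with a default relative tolerance of `1e-9`. Non-convergence raises an
  error naming the offending evaluation point.
* The integrand is continuous but loses derivative smoothness where the
  bracket vanishes: at both support edges (exponents $2\delta$, $\delta$
  and $\delta/m$ < 1 give infinite one-sided slope) and, if
  $x_{\min} < 0 < x_{\max}$, at the interior root $x = 0$. All such points
  become panel boundaries, and the fitting engine maps the adjacent panels
  through $x = \text{edge} \pm s^2$, which roughly doubles the local
  exponent before applying a fixed 24-node Gauss–Legendre rule.
* That fixed-order panel rule is the optimizer's objective engine: one
  least-squares evaluation costs a single vectorized rate evaluation over
  all panels. Tests pin it against the adaptive integrator at $10^{-7}$
  relative and against a $10^6$-panel trapezoid reference.
* The plateau value is computed lazily on the first evaluation beyond
  `x_max` and cached on the curve object.

## Fitting and model comparison

`fit_growth()` minimises the residual sum of squares between observed
sizes and the cumulative curve with the Nelder–Mead simplex
(`stats::optim`), the standard derivative-free choice given the
non-smooth endpoint behaviour. Design choices, all of which matter for
reproducibility:

* **Transforms.** `a`, `m`, `delta` are optimised on the log scale;
  `x_max` as $L + e^{u}$ with $L$ the last time with a nonzero observed
  size (growth cannot have ended before something was measured); a free
  `x_min` as $M - e^{v}$ with $M$ the first such time. Nelder–Mead is
  unconstrained; the transforms enforce the domain exactly.
* **Restarts.** A deterministic grid of starting values:
  $x_{\max,0} \in \{1.05, 1.2, 1.5\}\,L$, $m_0 \in \{1,2,4\}$,
  $\delta_0 \in \{0.5,1,2\}$ for the MBE, with $a_0$ scaled so the
  curve's asymptote matches the largest observed size (9 starts for the
  BE, 27 for the MBE). Requesting more restarts appends seed-controlled
  ±20% log-scale jitters of the grid, so a fit is bit-reproducible given
  `(series, model, fix_x_min, seed, n_restarts)`.
* **Convergence.** Relative objective tolerance $10^{-10}$, at most 5000
  simplex iterations per restart. (`optim`'s Nelder–Mead exposes an
  objective-scale tolerance only; parameter-scale assurance comes from the
  multi-start.)
* **Nesting.** An MBE fit always also evaluates — and polishes — the
  converged BE solution with $\delta = 1$ as a candidate. The reported
  MBE RSS therefore can never exceed the BE RSS, making the model
  comparison coherent by construction.
* Observations later than the fitted `x_max` are predicted at the plateau,
  never dropped.

`compare_models()` computes
$\mathrm{APE} = |\mathrm{RMSE}_{BE}-\mathrm{RMSE}_{MBE}| /
\mathrm{RMSE}_{BE} \times 100\%$ with the *simpler model's* RMSE as the
denominator, and prefers the MBE only when APE strictly exceeds 5% *and*
its RMSE is actually lower; at APE exactly 5%, or any tie, the BE wins.
An exact-zero BE RMSE makes the APE undefined and raises an error — which
is also why judging the rule on *noiseless* synthetic data is meaningless:
both RMSEs are then optimizer noise near zero and their ratio is
arbitrary. Tests of the rule use data with realistic measurement noise.

## The synthetic-data generator

`simulation_design()` + `simulate_growth_series()` generate trajectories
with known truth. Two canonical designs mirror common field protocols:

* `design_crops_like()`: 15 sampling dates every 5 days from day 14 to 84
  after sowing, 20 replicate individuals per date (destructive biomass
  sampling of annual crops). Default truth: growth ends at day 90 —
  shortly after the last sampling date, as happens when a season is
  surveyed to (near) maturity — with $\delta = 1.4$, $m = 3$ and an
  asymptote of ~150 g.
* `design_bamboo_like()`: daily heights for 30 days post-emergence, then
  every 3 days to day 60, one culm per date; default truth plateaus near
  6 m after 50 days.

The default noise model is additive Gaussian with standard deviation 2%
of the asymptotic size (measurement scatter); a multiplicative log-normal
option covers size-proportional error. Negative draws are clamped to zero.
What the generator does *not* emulate: between-individual variation in the
growth parameters themselves (random effects), autocorrelated measurement
error, or missing data. Passing parameter-recovery tests on these
simulations therefore demonstrates estimator correctness under the stated
error model, not robustness to individual heterogeneity in real data.
Under the crop design the median relative error of the recovered `x_max`
is ~4% across simulations — information-limited, since the true end of
growth lies beyond the last sampling date (the fitted RSS is routinely
*below* the RSS at the generating parameters).

## Leaf outlines

An ovate lamina can be described as two single-valued half-width curves of
the position $x$ along the length axis, and the MBE's skewed bell is a
natural profile for them. `register_leaf()` rigidly moves an outline so
the length axis — the segment between the two boundary points at maximum
pairwise distance — is the x-axis with the base at the origin.
Orientation is decided by the width profile: because the MBE half-width
(with $x_{\min}=0$ at the base) always peaks in the apical half of its
support, the registration maps the outline's width-weighted centroid
toward the apex end. This is the only orientation the model can represent,
and it makes simulation → registration → fitting a consistent round trip;
for a leaf whose widest section is anatomically near the petiole, the
model's "base" coordinate is simply the blunt end of the profile, whatever
the botanical label.

`fit_leaf()` then fits `(a, m, delta)` per margin with $x_{\min}=0$ and
$x_{\max}$ *fixed* at the observed leaf length — the apex is directly
observed, and freeing `x_max` confounds it with `delta`. The objective is
the vertical (half-width) residual sum of squares, not perpendicular
distance: simpler, consistent with treating the margins as functions of
$x$, and exact in the round-trip tests, though it can differ from a
perpendicular-distance fit on strongly curved outlines. The symmetric
variant fits one parameter set to $|y|$ of all points and is nested in the
asymmetric fit by construction.

## Problem sizes and limitations

The test suite and the acceptance script size their simulations for tight
oracles rather than breadth: 100 parameter draws × $10^4$ grid points for
the reduction identity, 50 draws for the Beta-integral oracle, 50
simulated seasons for noisy recovery, 120-point outlines for the leaf
round trip. Known limitations:

* No standard errors or information criteria are produced — model
  adjudication is deliberately the RMSE/APE rule from the applied
  literature, and uncertainty quantification is out of scope.
* The end-of-growth estimate is only as good as late-season data; with a
  truncated series it is systematically uncertain (and historically
  overestimated), which the APE rule does not penalise.
* A single trajectory per fit: replicated designs are pooled, not
  modelled hierarchically.
* The temperature reading of the same equations (development rate vs
  temperature) shares the mathematics but is not given a dedicated
  interface.
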