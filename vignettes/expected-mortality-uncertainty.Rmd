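---
title: "Propagating expected-mortality uncertainty into relative survival and loss in life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating expected-mortality uncertainty into relative survival and loss in life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population-based cancer survival is usually summarised in a *relative
survival* framework.  The all-cause mortality rate of the cancer cohort,
$h(t \mid Z)$, is decomposed into an expected rate $h^*(t \mid Z_2)$ —
the general-population mortality matched on age, sex, calendar year and
possibly region — and an excess rate attributable to the cancer:

$$\lambda(t \mid Z_1) = h(t \mid Z) - h^*(t \mid Z_2).$$

The expected rates come from a population life table ("popmort") and are
conventionally treated as *known constants*: all reported uncertainty in
relative survival (RS) and in loss in life expectancy (LLE) derives from
the cancer cohort alone.  That convention is defensible when the life
table summarises an entire national population, but becomes questionable
when rates are stratified by many variables (leaving few person-years
per cell) or built from a sample of the population.

`relsurvuq` implements a pipeline that quantifies how much this
convention understates standard errors: it smooths the life table with a
Poisson spline model, draws parametric-bootstrap replicates of the whole
rate surface from the model's estimated coefficient distribution, refits
the relative-survival model against every replicate, pools with Rubin's
rules, and reports the *relative % precision*

$$RP = 100\left\{\left(\frac{SE_{boot}}{SE_{conv}}\right)^2 - 1\right\}$$

per measure.  Because the real registry inputs of such studies cannot be
redistributed, the package ships a synthetic-data generator that
emulates their statistical structure with a fully known truth.

## Models

### The relative-survival model

The excess hazard is modelled with a flexible parametric survival model
on the log cumulative excess hazard scale,

$$\ln \Lambda(t \mid Z_1) = s(\ln t \mid \gamma, k_0) + \beta Z_1,$$

where $s$ is a restricted cubic spline.  Defaults follow standard
practice for cancer-registry analyses: 5 df for the baseline spline in
log time, 4 df for age at diagnosis, a sex main effect, and
time-varying effects formed as interactions of a 3-df spline of log
time with every age basis column and with sex.  Region is never a model
covariate: excess mortality is assumed common across regions even when
expected rates are region-stratified.

Relative survival follows as $RS(t) = \exp(-\Lambda(t))$, and the
likelihood of subject $i$ with follow-up $t_i$ and death indicator
$d_i$ is

$$\ell_i = d_i \ln\{h^*_i + \lambda(t_i)\} - \Lambda(t_i),$$

with $h^*_i$ looked up at the attained age and calendar year at exit
and treated as fixed.  $\lambda(t) = \Lambda(t)\,\eta'(\ln t)/t$ with
$\eta$ the spline predictor, so the likelihood, its gradient, and the
observed information are all analytic in the spline bases.

Knot placement: boundary knots at the data extremes, interior knots at
equally spaced quantiles — of uncensored log event times for the time
splines, of age at diagnosis for the age spline (quantiles by linear
interpolation of the empirical CDF, so placement is deterministic).
The model is mildly knot-dependent, which is why fits serialise their
knots.  Internally, age enters its spline on an affine $[-1, 1]$ axis:
raw truncated-power cubes over an 80-year age range crossed with time
splines produce a numerically singular information matrix, and the
rescaling is a lossless reparameterisation.

Optimisation is BFGS on the analytic-gradient likelihood followed by
damped Newton steps using the finite-difference Hessian of the
gradient.  Convergence is declared when either the score sup-norm falls
below $10^{-4}$ or the Newton decrement $g'H^{-1}g/2$ — the expected
log-likelihood gain of a full Newton step — falls below $10^{-6}$; the
second, scale-aware criterion matters because for log-likelihoods of
magnitude $10^3$–$10^4$ the numerically attainable score floor can sit
above any fixed absolute threshold while the fit is already within
$\sim 10^{-3}$ standard errors of the optimum.  The likelihood is only
defined where $h^*_i + \lambda(t_i) > 0$ for every death; outside that
region the objective is assigned a large penalty so line searches back
off.  Warm starts (used for every replicate refit) skip the all-cause
pre-fit that otherwise seeds the optimiser; refits to resampled or
perturbed data can reuse a reference fit's knots, which is also what
the delta-method standard errors condition on.

### Life expectancy and its loss

Loss in life expectancy for covariates $Z$ is

$$LLE(Z) = \int_0^{H} S^*(u \mid Z_2)\,du
         - \int_0^{H} RS(u \mid Z_1)\, S^*(u \mid Z_2)\,du,$$

extrapolating the two factors separately: $S^*$ from the life table,
$RS$ from the fitted model, whose restricted cubic spline is *linear in
$\ln t$ beyond the last knot* — this linear tail is the extrapolation
mechanism.  The expected hazard is piecewise constant on single-year
attained-age × calendar-year bands, so $S^*$ and $LE_P = \int S^*$ are
computed exactly band by band (no quadrature error).  $LE_C = \int RS
\cdot S^*$ uses composite Gauss–Legendre quadrature within each band:
the integrand is smooth inside bands, with kinks only at band edges.

Numerical choices, all surfaced in results:

* **Horizon.** The idealised $\int_0^\infty$ is truncated at
  $H = \min(110 - \text{age at diagnosis}, 80)$ years.  Life-table
  rates beyond the tabulated age/year ranges persist at their boundary
  values (clamping), which keeps extrapolated $S^*$ proper; the
  reported `tail_bound` $= S^*(H)/h^*(H)$ bounds the truncated mass.
  For the youngest profiles the bound can reach a few tenths of a year;
  it affects $LE_P$ and $LE_C$ nearly equally and cancels to first
  order in their difference and in all RP comparisons.
* **Quadrature.** 10 nodes per band with doubling refinement until the
  LLE changes by less than $10^{-6}$ years (error if not converged
  within 4 doublings) for one-off conditional predictions; the
  replicate loop uses a fixed 5 nodes per band, which already agrees
  with the refined value to about $10^{-5}$ years — far below reporting
  precision — at half the cost.
* **Standard errors.** Delta method over the model coefficients only
  (expected rates fixed, so $LE_P$ contributes no variance), using the
  analytic gradient $\partial LLE/\partial\theta = \int w\,S^* RS\,
  \Lambda\, x(u)\,du$ — exact, and identical machinery for conditional
  and marginal estimates.

Marginal (regression-standardised) estimates average the conditional
predictions over the cohort's empirical covariate distribution; the
marginal engine applies the identical per-subject band structure, so
the marginal point estimate equals the arithmetic mean of the
per-subject conditional estimates by construction.  Marginal confidence
intervals are symmetric on the natural scale (truncated to $[0,1]$ for
RS); conditional RS intervals are computed on the log cumulative excess
hazard scale and back-transformed.

### The expected-mortality model and its bootstrap

Death counts per life-table cell are smoothed by Poisson regression
with log person-years offset: sex, restricted cubic splines of age
(5 df) and calendar year (3 df), and all pairwise interactions — sex ×
each age basis column, sex × each year basis column, and the full
age ⊗ year basis tensor.  The phrase "pairwise interactions of age,
sex and year" admits several readings; the maximal pairwise form is
implemented, and the df are configurable.  Separate models are fitted
per region.  Age and year are rescaled to $[-1,1]$ for the same
conditioning reason as above.  The model's predictions form the
*underlying* rate table used as the fixed expected mortality of the
conventional analysis, so conventional and bootstrap analyses differ
only in whether coefficient uncertainty is propagated.

Replicate tables draw coefficients from $N(\hat\beta, \hat\Sigma)$
(inverse Fisher information), factorised by symmetric
eigendecomposition with negative eigenvalues clipped at zero.  Each
region draws independently from a deterministic child seed of the
master seed.  Dividing deaths and person-years by a factor $k$ leaves
$\hat\beta$ unchanged and scales $\hat\Sigma$ by $k$ exactly — the
mechanism that makes replicate rate spread scale as $\sqrt{k}$ and
drives the entire size-reduction design.

### Pooling and the scenario grid

For each of $M$ replicate tables the relative-survival model is refitted
and every measure re-predicted with its SE.  Rubin's rules combine them:
pooled mean, within-variance $V_W$ (mean squared SE), between-variance
$V_B$, and $V_p = V_W + V_B + V_B/M$.  Pooling is on the natural scale
of each measure (proportion for RS, years for LLE), as the variance
identities are stated on that scale; RP may be slightly negative
because $SE_{conv}$ is the conventional model's own SE rather than
$\sqrt{V_W}$.  Replicates whose refit fails are dropped and counted; a
scenario with more than 1% failures is invalid.

The scenario grid crosses cohort size (full / 10%), life-table
population (full, 1/10, 1/200, 1/2000) and region stratification,
labelled A–J with A = full cohort, full-size national table, no region.

## The synthetic world

`synth_params()` fixes a study-scale world chosen once:

* **Life table**: sex × ages 18–99 × years 1975–2017, ≈ 9 million
  person-years per calendar year allocated by a pyramid flat to age 60
  and declining linearly to near zero at 100.  True rates are
  Gompertz-like: $0.02\,e^{0.088(\text{age}-70)}$ per year for men in
  2000, women ×$e^{-0.45}$, a 1%/year secular decline, optional
  mean-zero region contrasts (SD 0.1 on the log scale).  Counts are
  Poisson draws around rate × person-years.
* **Cohort**: 3400 patients, ages 50–95 (scaled Beta(1.8, 2.2), mean
  ≈ 70), half female, diagnosed uniformly through 2006, followed to the
  end of 2017.  Other-cause death times are inverted through each
  subject's piecewise-constant *true* rates — using the true surface
  rather than the sampled table keeps the exchangeability assumption of
  the framework exactly true in the synthetic world.  Excess death
  times are Weibull, shape 0.8 (declining excess hazard, as for colon
  cancer), scale 14.3 years, log-linear effects 0.012/year of age and
  −0.05 for women: 5-year relative survival ≈ 0.6–0.7, LLE from ≈ 3
  years at age 85 to ≈ 16–19 at age 55 (the young-age values run a few
  years above typical registry estimates because the Weibull excess
  model has no cure fraction; no result here depends on that
  magnitude).
* All randomness flows through deterministic child streams of one
  master seed.

What the generator does *not* emulate: real demography and migration,
cohort effects in the mortality surface beyond the log-linear trend,
non-administrative censoring, regional differences in excess (as in
the study design, excess mortality is region-free).  Passing tests
therefore demonstrate the statistical machinery — not that any
particular registry would show the same RP values.

## Problem sizes used in the shipped checks

The package's own test battery runs the full pipeline at the study
scale it emulates: the headline scenario uses the national-scale table,
the n = 3400 cohort and M = 200 replicates (M = 1000 remains the
default for production runs; at M = 200 the Monte-Carlo error of RP is
a few percent of its value, ample for a sub-1% bound).  The
size-reduction monotonicity sweep runs the same national table through
reduction factors 1/10/200/2000 with an n = 1000 cohort at M = 200;
bootstrap-versus-delta comparisons use a 500,000 person-year world
with n = 500–600 cohorts; exact limits use closed-form flat-rate
tables.  The coverage experiment fits 100 independent n = 3400
cohorts against the fixed true rate surface.

## Known limitations

* Delayed entry, cure models, alternative link scales and
  age-standardised (external-weight) RS are out of scope.
* The conventional marginal CI is natural-scale symmetric; for marginal
  RS very near 0 or 1 a transformed scale would be preferable.
* Knot locations are data-driven defaults; sensitivity to placement is
  not explored automatically.
* With extreme size reductions (factor 2000) individual replicate rate
  surfaces can be wild; failed refits are dropped and counted, and the
  1% failure guard aborts scenarios where this becomes material.
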