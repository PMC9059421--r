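# relsurvuq

Does treating general-population mortality rates as *known constants*
understate the standard errors of relative survival and loss in life
expectancy?  `relsurvuq` implements the full machinery needed to answer
that question for any cohort/life-table pair, and a synthetic study
world to exercise it end to end.

It is aimed at biostatisticians working with population-based cancer
registry data who estimate, from a flexible parametric relative-survival
model,

- **5-year relative survival**, `RS(t|Z₁) = exp(−Λ(t|Z₁))` with
  `ln Λ(t|Z₁) = s(ln t | γ, k₀) + βZ₁` (restricted cubic splines, with
  time-varying effects),
- **loss in life expectancy**,
  `LLE(Z) = ∫ S*(u|Z₂) du − ∫ RS(u|Z₁) S*(u|Z₂) du`,

and want to know how much wider their confidence intervals would be if
the uncertainty of the expected rates `h*(t|Z₂)` (from a "popmort" life
table) were propagated.  The pipeline:

1. **Smooth** the life table by Poisson regression of deaths on sex ×
   rcs(age) × rcs(year) with all pairwise interactions and log
   person-years offset (per region, if stratified); use the predictions
   as the *underlying* fixed rates.
2. **Perturb**: draw M replicate coefficient vectors from
   N(β̂, Σ̂) and turn each into a full replicate rate table.
3. **Refit** the relative-survival model against every replicate table
   and re-predict each measure with its delta-method SE.
4. **Pool** with Rubin's rules: `V_p = V_W + V_B + V_B/M`, and report
   the relative % precision `RP = 100((SE_boot/SE_conv)² − 1)` per
   measure — conditionally at ages 55/65/75/85 × sex and marginally
   (regression standardisation over the cohort).

A scenario grid (A–J) crosses cohort size, life-table population size
(full, 1/10, 1/200, 1/2000) and region stratification.

## Worked example

```r
library(relsurvuq)

params  <- synth_params(py_total_per_year = 5e5, cohort_n = 600, seed = 42)
popmort <- simulate_popmort(params)                 # sampled life table
cohort  <- simulate_cohort(params, true_rate_table(params))

rates      <- fit_poisson_rates(popmort)
underlying <- predict_underlying(rates)
fit <- fit_fpm(cohort, underlying, fpm_config())
predict_rs(fit, list(age_dx = 75, sex = "male"), t = 5)
lle_conditional(fit, underlying,
                list(age_dx = 75, sex = "male", year_dx = 2006.5))
```

```
  t  estimate         se    ci_low   ci_high
1 5 0.6661444 0.04545052 0.5685801 0.7465422
LLE: 6.640 years (SE 0.530, 95% CI 5.602-7.678)
  LE_pop 13.980, LE_cancer 7.340; horizon 35.0 y (tail bound 0.04)
```

So for men diagnosed at 75 in this 500,000 person-year world, an
estimated 67% would survive 5 years in the absence of other-cause
mortality, and diagnosis costs them on average 6.6 of the 14.0 years a
matched general-population male would still live — with SEs that so far
ignore any uncertainty in the life table.  Propagating it (scenario C:
full cohort, life table from 1/200 of the population):

```r
rep_c <- run_scenario(cohort, popmort, scenario_spec("C", M = 50, seed = 7))
subset(report_table(rep_c), method == "bootstrap" & (age %in% 75 | sex == "marginal"),
       c(measure, age, sex, estimate, se, rp))
```

```
 measure age      sex   estimate         se         rp
     rs5  75     male  0.6669581 0.04690521   6.503625
     rs5  75   female  0.6686579 0.04392852   5.454150
     rs5  NA marginal  0.6567689 0.02334633   6.456285
     lle  75     male  6.5614731 0.95387397 224.257957
     lle  75   female  8.8770546 1.27793645 200.896841
     lle  NA marginal 10.4496229 0.91066831 183.456159
```

With rates built from only ~2,500 people, ignoring their uncertainty
understates the RS variance by ~6% — and the LLE variance by a factor
of ~3 (RP ≈ 200%): the conventional LLE standard error of 0.53 years
becomes 0.95 years.  With the full-size table (scenario A) RP drops
below 1% for every measure, i.e. the conventional assumption is then
harmless.

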