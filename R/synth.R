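#' Parameters of the synthetic study world
#'
#' Defines a synthetic stand-in for the study's two (non-shareable)
#' inputs: a national-scale population life table and a cancer cohort
#' diagnosed in a single year with roughly twelve years of follow-up.
#' The population mortality truth is Gompertz-like on the log scale —
#' linear in age, with a sex contrast, a gentle calendar-year improvement
#' trend and optional region contrasts — and the cancer's excess hazard
#' is Weibull with log-linear age and sex effects, so every true
#' quantity (rates, expected survival, relative survival, loss in life
#' expectancy) has a closed or cheaply computable form.
#'
#' Default magnitudes are chosen to resemble a Nordic-scale country and
#' a colon-cancer-like disease: about 9 million person-years per calendar
#' year, mortality near 0.02/year at age 70 for men in 2000 doubling
#' roughly every 8 years of age, women about 35\% lower, a 1\% annual
#' secular decline; a cohort of 3400 patients aged 50-95 diagnosed in
#' 2006 and censored administratively at the end of 2017; and a
#' decreasing Weibull excess hazard giving 5-year relative survival
#' around 0.6-0.7 and loss in life expectancy from roughly 2 years at
#' age 85 to over 10 years at age 55.
#'
#' @param pop_alpha Named vector of log-rate coefficients:
#'   \code{intercept} (log rate at the reference age/sex/year),
#'   \code{age} (per year of age above 70), \code{female} (sex
#'   contrast), \code{year} (per calendar year after 2000).
#' @param py_total_per_year Total person-years across the grid per
#'   calendar year.
#' @param age_range,year_range Integer ranges of the life-table grid.
#' @param cohort_n Cohort size.
#' @param age_dx_range Support of the age-at-diagnosis distribution
#'   (a scaled Beta(1.8, 2.2)).
#' @param dx_year Diagnosis calendar year (diagnoses spread uniformly
#'   through it).
#' @param censor_year Last calendar year of follow-up; administrative
#'   censoring at its end.
#' @param excess_shape,excess_scale Weibull shape/scale of the baseline
#'   excess hazard (shape < 1 gives the declining excess hazard typical
#'   of colon cancer).
#' @param excess_beta_age Log excess-hazard effect per year of age above
#'   70.
#' @param excess_beta_female Log excess-hazard sex contrast.
#' @param region_sd Standard deviation of mean-zero region contrasts on
#'   the log mortality rate (used when regions are requested).
#' @param seed Master seed; all generator stages derive child streams
#'   from it.
#' @return An object of class \code{synth_params}.
#' @export
synth_params <- function(pop_alpha = c(intercept = log(0.02), age = 0.088,
                                       female = -0.45, year = -0.01),
                         py_total_per_year = 9e6,
                         age_range = c(18L, 99L),
                         year_range = c(1975L, 2017L),
                         cohort_n = 3400L,
                         age_dx_range = c(50, 95),
                         dx_year = 2006L,
                         censor_year = 2017L,
                         excess_shape = 0.8,
                         excess_scale = 14.3,
                         excess_beta_age = 0.012,
                         excess_beta_female = -0.05,
                         region_sd = 0.1,
                         seed = 1L) {
  stopifnot(all(c("intercept", "age", "female", "year") %in%
                  names(pop_alpha)),
            py_total_per_year > 0, cohort_n >= 50,
            excess_shape > 0, excess_scale > 0,
            age_dx_range[1] >= age_range[1],
            age_dx_range[2] <= age_range[2])
  structure(list(pop_alpha = pop_alpha,
                 py_total_per_year = py_total_per_year,
                 age_range = as.integer(age_range),
                 year_range = as.integer(year_range),
                 cohort_n = as.integer(cohort_n),
                 age_dx_range = age_dx_range,
                 dx_year = as.integer(dx_year),
                 censor_year = as.integer(censor_year),
                 excess_shape = excess_shape, excess_scale = excess_scale,
                 excess_beta_age = excess_beta_age,
                 excess_beta_female = excess_beta_female,
                 region_sd = region_sd, seed = as.integer(seed)),
            class = "synth_params")
}

# Age pyramid weight: flat to age 60, linear decline to near zero at 100.
age_pyramid_weight <- function(age) pmax(pmin(1, (100 - age) / 40), 0.01)

# Region contrasts (log scale) and population shares, reproducible from
# the master seed; one dominant region plus smaller ones.
synth_regions <- function(params, region_count) {
  if (region_count <= 1L)
    return(list(labels = NULL, contrast = 0, share = 1))
  labels <- sprintf("R%02d", seq_len(region_count))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(child_seed(params$seed, 3))
  contrast <- stats::rnorm(region_count, 0, params$region_sd)
  contrast <- contrast - mean(contrast)
  share <- 2^seq(0, -(region_count - 1) / 2, length.out = region_count)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(labels = labels, contrast = contrast, share = share / sum(share))
}

# True log mortality rate surface.
synth_log_rate <- function(params, age, female, year, region_contrast = 0) {
  a <- params$pop_alpha
  a[["intercept"]] + a[["age"]] * (age - 70) + a[["female"]] * female +
    a[["year"]] * (year - 2000) + region_contrast
}

#' Life table carrying the true (noise-free) rate surface
#'
#' Builds the life table whose rates are exactly the generator's true
#' Gompertz-like surface, with \code{deaths = rate * person_years}
#' (bookkeeping, not sampled counts).  Other-cause death times in
#' [simulate_cohort()] are drawn against this surface, so the simulated
#' world satisfies the exchangeability assumption of the
#' relative-survival framework exactly.
#'
#' @inheritParams simulate_popmort
#' @return A [lifetable()].
#' @export
true_rate_table <- function(params, region_count = 1L) {
  g <- synth_grid(params, region_count)
  df <- data.frame(g$frame[c("sex", "age", "year",
                             if (region_count > 1) "region")],
                   deaths = g$rate * g$frame$person_years,
                   person_years = g$frame$person_years)
  lifetable(df)
}

synth_grid <- function(params, region_count) {
  ages <- seq(params$age_range[1], params$age_range[2])
  years <- seq(params$year_range[1], params$year_range[2])
  reg <- synth_regions(params, region_count)
  frame <- expand.grid(sex = c("male", "female"), age = ages, year = years,
                       region_i = seq_len(max(1L, region_count)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- age_pyramid_weight(frame$age)
  wsum <- sum(age_pyramid_weight(ages)) * 2  # both sexes, one year, one region
  frame$person_years <- params$py_total_per_year * w / wsum *
    reg$share[frame$region_i]
  female <- as.numeric(frame$sex == "female")
  contrast <- if (region_count > 1) reg$contrast[frame$region_i] else 0
  rate <- exp(synth_log_rate(params, frame$age, female, frame$year, contrast))
  if (region_count > 1) frame$region <- reg$labels[frame$region_i]
  frame$region_i <- NULL
  list(frame = frame, rate = rate, regions = reg)
}

#' Simulate a stratified population life table
#'
#' Allocates person-years over the sex by age by year (by region) grid
#' according to the age pyramid and total person-years per year, then
#' draws death counts as Poisson with mean \code{true rate *
#' person_years}.  The true rate surface is the Gompertz-like log-linear
#' model of [synth_params()].
#'
#' @param params A [synth_params()].
#' @param region_count Number of regions (1 = no region column).
#' @return A [lifetable()] of sampled death counts.
#' @export
simulate_popmort <- function(params, region_count = 1L) {
  stopifnot(inherits(params, "synth_params"))
  g <- synth_grid(params, region_count)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(child_seed(params$seed, 1))
  deaths <- stats::rpois(nrow(g$frame), g$rate * g$frame$person_years)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  df <- data.frame(g$frame[c("sex", "age", "year",
                             if (region_count > 1) "region")],
                   deaths = deaths,
                   person_years = g$frame$person_years)
  lifetable(df)
}

#' Simulate a matched cancer cohort
#'
#' Draws, per subject: age at diagnosis (scaled Beta on the configured
#' range), sex (balanced), diagnosis date uniform within the diagnosis
#' year, and region (by population share) when \code{truth_table} is
#' region-stratified.  The time to other-cause death is generated by
#' inverse transform through the subject's piecewise-constant expected
#' rates from \code{truth_table} — exactly the exchangeability assumption
#' of the relative-survival framework — and the time to excess (cancer)
#' death from the Weibull excess model
#' \eqn{\Lambda_E(t) = (t/\sigma)^a \exp(x'\beta_E)}.  The observed time
#' is the minimum of the two latent times and administrative censoring at
#' the end of the censoring year; \code{event} indicates death from
#' either cause.
#'
#' @param params A [synth_params()].
#' @param truth_table A [lifetable()] carrying the expected-rate surface
#'   to simulate other-cause deaths from (normally the TRUE rate table,
#'   so the simulated world matches the relative-survival assumptions
#'   exactly).
#' @return Data frame of cohort records (\code{id}, \code{age_dx},
#'   \code{sex}, \code{year_dx}, (\code{region},) \code{time},
#'   \code{event}).
#' @export
simulate_cohort <- function(params, truth_table) {
  stopifnot(inherits(params, "synth_params"),
            inherits(truth_table, "lifetable"))
  n <- params$cohort_n
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(child_seed(params$seed, 2))
  r <- params$age_dx_range
  age_dx <- r[1] + (r[2] - r[1]) * stats::rbeta(n, 1.8, 2.2)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  year_dx <- params$dx_year + stats::runif(n)
  region <- if (truth_table$has_region) {
    reg <- synth_regions(params, length(truth_table$regions))
    sample(reg$labels, n, replace = TRUE, prob = reg$share)
  }
  u_other <- stats::runif(n)
  u_excess <- stats::runif(n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  censor <- params$censor_year + 1 - year_dx  # to end of censor_year
  horizon <- pmax(censor + 1, 115 - age_dx)   # latent-time support
  female <- as.numeric(sex == "female")
  xb <- params$excess_beta_age * (age_dx - 70) +
    params$excess_beta_female * female
  t_excess <- params$excess_scale *
    (-log(u_excess) * exp(-xb))^(1 / params$excess_shape)
  t_other <- invert_expected_many(truth_table, age_dx, sex, year_dx,
                                  region, -log(u_other), horizon)
  t_death <- pmin(t_other, t_excess)
  time <- pmin(t_death, censor)
  out <- data.frame(id = seq_len(n), age_dx = age_dx, sex = sex,
                    year_dx = year_dx, time = pmax(time, 1e-8),
                    event = as.numeric(t_death <= censor))
  if (truth_table$has_region) out$region <- region
  out
}

# Solve H*(t) = target along each subject's piecewise-constant hazard
# path (vectorised over subjects); beyond `horizon` the last band's rate
# persists, so the inversion always succeeds for positive rates.
invert_expected_many <- function(table, age_dx, sex, year_dx, region,
                                 target, horizon) {
  n <- length(age_dx)
  hmax <- max(horizon)
  k <- seq_len(ceiling(hmax) + 1L)
  cand <- cbind(outer(-(age_dx %% 1), k, `+`),
                outer(-(year_dx %% 1), k, `+`))
  cand <- pmin(pmax(cand, 0), horizon)
  E <- cbind(0, t(apply(cand, 1L, sort)), hmax + horizon * 0)
  E[, ncol(E)] <- horizon
  nb <- ncol(E) - 1L
  W <- E[, -1L, drop = FALSE] - E[, -ncol(E), drop = FALSE]
  mid <- (E[, -1L, drop = FALSE] + E[, -ncol(E), drop = FALSE]) / 2
  R <- matrix(lookup_rate(table, rep(sex, nb), age_dx + mid,
                          year_dx + mid,
                          if (table$has_region) rep(region, nb)),
              n, nb)
  Hc <- t(apply(R * W, 1L, cumsum))         # cum hazard at band ends
  Hc0 <- cbind(0, Hc[, -nb, drop = FALSE])  # ... at band starts
  b <- pmin(1L + rowSums(Hc < target), nb)  # first band reaching target
  ib <- cbind(seq_len(n), b)
  tt <- E[, -ncol(E), drop = FALSE][ib] + (target - Hc0[ib]) / R[ib]
  # target beyond the path's total hazard: last band's rate persists
  over <- target > Hc[, nb]
  tt[over] <- E[over, ncol(E)] +
    (target[over] - Hc[over, nb]) / R[over, nb]
  tt[R[ib] <= 0] <- Inf
  tt
}

#' True relative survival and loss in life expectancy
#'
#' Computes, for one profile, the generator's true 5-year-style relative
#' survival at \code{t} (closed-form Weibull excess survival
#' \eqn{RS(t) = \exp\{-(t/\sigma)^a e^{x'\beta_E}\}}) and the true loss
#' in life expectancy, integrating expected survival and
#' \eqn{RS \cdot S^*} against the TRUE rate surface (not a sampled
#' table) by composite Gauss-Legendre quadrature per life-table band.
#'
#' @param params A [synth_params()].
#' @param profile Profile with \code{age_dx}, \code{sex},
#'   \code{year_dx}, optionally \code{region}.
#' @param t Time for the relative-survival truth (default 5 years).
#' @param horizon Integration horizon; \code{NULL} = the default rule
#'   \code{min(110 - age_dx, 80)}.
#' @param region_count Regions in the true surface (match the simulated
#'   table).
#' @param quad_nodes Gauss-Legendre nodes per band.
#' @return List with \code{rs}, \code{lle}, \code{le_p}, \code{le_c}.
#' @export
true_values <- function(params, profile, t = 5, horizon = NULL,
                        region_count = 1L, quad_nodes = 10L) {
  stopifnot(inherits(params, "synth_params"))
  pr <- as_profile_df(profile)[1, , drop = FALSE]
  truth <- true_rate_table(params, region_count)
  female <- as.numeric(as.character(pr$sex) == "female")
  xb <- params$excess_beta_age * (pr$age_dx - 70) +
    params$excess_beta_female * female
  rs_fun <- function(u) exp(-(u / params$excess_scale)^params$excess_shape *
                              exp(xb))
  H <- if (is.null(horizon)) default_horizon(pr$age_dx) else horizon
  lep <- life_expectancy_pop(truth, pr, H)
  edges <- band_edges(pr$age_dx[1], pr$year_dx[1], H)
  gl <- gl01(as.integer(quad_nodes))
  le_c <- 0
  Hc <- cum_expected_hazard(truth, pr, edges)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  r <- lookup_rate(truth, pr$sex[1], pr$age_dx[1] + mid,
                   pr$year_dx[1] + mid,
                   if (truth$has_region) pr$region[1])
  for (b in seq_along(mid)) {
    w <- edges[b + 1] - edges[b]
    if (w <= 0) next
    u <- edges[b] + w * gl$x
    s <- exp(-(Hc[b] + r[b] * (u - edges[b])))
    le_c <- le_c + w * sum(gl$w * rs_fun(u) * s)
  }
  list(rs = rs_fun(t), lle = lep$le_p - le_c, le_p = lep$le_p, le_c = le_c)
}
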