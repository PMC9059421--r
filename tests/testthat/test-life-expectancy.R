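test_that("expected survival matches closed form and a Riemann oracle", {
  lt <- flat_table(0.02)
  pr <- list(age_dx = 60.3, sex = "male", year_dx = 2006.4)
  expect_equal(expected_survival(lt, pr, 5), exp(-0.1), tolerance = 1e-12)
  expect_equal(expected_survival(lt, pr, 0), 1)

  # non-flat table: left-endpoint Riemann product with step 1e-3
  w <- small_world()
  tgrid <- c(0.7, 3.2, 11.9, 25)
  S <- expected_survival(w$truth, pr, tgrid)
  h <- 1e-3
  u <- seq(0, 25 - h, h)
  r <- lookup_rate(w$truth, "male", pr$age_dx + u, pr$year_dx + u)
  Sr <- exp(-cumsum(r * h))
  expect_equal(S, Sr[round(tgrid / h)], tolerance = 1e-6)

  # non-increasing, equal to 1 at t = 0, across random profiles
  set.seed(3)
  for (i in 1:50) {
    prr <- list(age_dx = runif(1, 50, 95),
                sex = sample(c("male", "female"), 1),
                year_dx = 2006 + runif(1))
    Si <- expected_survival(w$truth, prr, seq(0, 40, 0.37))
    expect_equal(Si[1], 1)
    expect_true(all(diff(Si) <= 0))
  }
})

test_that("population life expectancy integrates the bands exactly", {
  lt <- flat_table(0.05, year_range = c(1995, 2100))
  pr <- list(age_dx = 40.2, sex = "female", year_dx = 2000.7)
  lep <- life_expectancy_pop(lt, pr, 1000)
  expect_equal(lep$le_p, 20, tolerance = 1e-6)

  # piecewise-exponential exactness: refining the partition changes nothing
  w <- small_world()
  pr2 <- list(age_dx = 72.6, sex = "male", year_dx = 2006.2)
  lep2 <- life_expectancy_pop(w$truth, pr2, 30)
  edges <- sort(unique(c(relsurvuq:::band_edges(pr2$age_dx, pr2$year_dx, 30),
                         seq(0.25, 29.75, 0.5))))
  refined <- 0
  for (b in seq_len(length(edges) - 1)) {
    m <- (edges[b] + edges[b + 1]) / 2
    r <- lookup_rate(w$truth, "male", pr2$age_dx + m, pr2$year_dx + m)
    S0 <- expected_survival(w$truth, pr2, edges[b])
    wdt <- edges[b + 1] - edges[b]
    refined <- refined + S0 * (1 - exp(-r * wdt)) / r
  }
  expect_equal(lep2$le_p, refined, tolerance = 1e-12)

  # doubling all rates lowers life expectancy
  double <- w$truth
  double$data$deaths <- 2 * double$data$deaths
  double <- lifetable(double$data)
  expect_lt(life_expectancy_pop(double, pr2, 30)$le_p, lep2$le_p)
})

test_that("constant-hazard loss in life expectancy has its closed form", {
  mu <- 0.05
  nu <- 0.05
  lt <- flat_table(mu, age_range = c(30, 40), year_range = c(2000, 2005))
  fit <- exponential_rs_fit(nu)
  pr <- list(age_dx = 35, sex = "male", year_dx = 2002)
  res <- lle_conditional(fit, lt, pr, horizon = 400, refine = FALSE)
  expect_equal(res$le_p, 1 / mu, tolerance = 1e-4)
  expect_equal(res$le_c, 1 / (mu + nu), tolerance = 1e-4)
  expect_equal(res$lle, 1 / mu - 1 / (mu + nu), tolerance = 1e-4)
  expect_equal(res$lle, res$le_p - res$le_c)  # additivity, exact
  expect_gte(res$se, 0)
})

test_that("zero excess hazard gives zero loss in life expectancy", {
  w <- small_world()
  fit <- exponential_rs_fit(1e-12)
  pr <- list(age_dx = 70, sex = "female", year_dx = 2006.5)
  res <- lle_conditional(fit, w$truth, pr, refine = FALSE)
  expect_equal(res$lle, 0, tolerance = 1e-8)
  expect_true(is.finite(res$se))
})

test_that("quadrature refinement converges on a fitted example", {
  w <- small_world()
  fit <- small_fit()
  pr <- list(age_dx = 75, sex = "male", year_dx = 2006.5)
  r10 <- lle_conditional(fit, w$truth, pr, quad_nodes = 10, refine = FALSE)
  r20 <- lle_conditional(fit, w$truth, pr, quad_nodes = 20, refine = FALSE)
  r40 <- lle_conditional(fit, w$truth, pr, quad_nodes = 40, refine = FALSE)
  expect_lt(abs(r40$lle - r20$lle), 1e-6)
  refined <- lle_conditional(fit, w$truth, pr)  # with refinement
  expect_lt(refined$quad_error, 1e-6)
  expect_equal(refined$lle, r20$lle, tolerance = 1e-5)
  expect_equal(r10$lle, r40$lle, tolerance = 1e-4)
})

test_that("marginal LLE equals the mean of per-subject conditional LLE", {
  w <- small_world()
  fit <- small_fit()
  sub <- w$cohort[seq_len(40), ]
  m <- lle_marginal(fit, w$truth, sub, quad_nodes = 5)
  cond <- vapply(seq_len(nrow(sub)), function(i)
    lle_conditional(fit, w$truth, sub[i, ], quad_nodes = 5,
                    refine = FALSE)$lle, 0)
  expect_equal(m$lle, mean(cond), tolerance = 1e-10)
  expect_equal(attr(m, "per_subject"), cond, tolerance = 1e-10)

  # homogeneous cohort: marginal equals conditional including SE
  hom <- sub
  hom$age_dx <- 70
  hom$sex <- "male"
  hom$year_dx <- 2006.5
  mh <- lle_marginal(fit, w$truth, hom, quad_nodes = 5)
  ph <- lle_conditional(fit, w$truth,
                        list(age_dx = 70, sex = "male", year_dx = 2006.5),
                        quad_nodes = 5, refine = FALSE)
  expect_equal(mh$lle, ph$lle, tolerance = 1e-10)
  expect_equal(mh$se, ph$se, tolerance = 1e-8)
})

test_that("LLE varies by region exactly when the table is region-stratified", {
  p <- synth_params(py_total_per_year = 4e5, cohort_n = 200, seed = 12,
                    region_sd = 0.3)
  truth_r <- true_rate_table(p, region_count = 2)
  ch <- simulate_cohort(p, truth_r)
  fit <- fit_fpm(ch, truth_r, fpm_config(baseline_df = 3, age_df = 2,
                                         tvc_df = 0))
  base <- list(age_dx = 75, sex = "male", year_dx = 2006.5)
  l1 <- lle_conditional(fit, truth_r, c(base, region = truth_r$regions[1]),
                        refine = FALSE)
  l2 <- lle_conditional(fit, truth_r, c(base, region = truth_r$regions[2]),
                        refine = FALSE)
  expect_gt(abs(l1$lle - l2$lle), 1e-3)
  # collapsing regions removes the dependence
  nat <- collapse_regions(truth_r)
  fit_n <- fit_fpm(ch, nat, fpm_config(baseline_df = 3, age_df = 2,
                                       tvc_df = 0))
  ln <- lle_conditional(fit_n, nat, base, refine = FALSE)
  expect_s3_class(ln, "lle_result")
})

test_that("extending the horizon moves LLE by less than the tail bound", {
  w <- small_world()
  fit <- small_fit()
  pr <- list(age_dx = 80, sex = "male", year_dx = 2006.5)
  a <- lle_conditional(fit, w$truth, pr, horizon = 30, refine = FALSE)
  b <- lle_conditional(fit, w$truth, pr, horizon = 60, refine = FALSE)
  expect_lt(abs(b$lle - a$lle), a$tail_bound)
})
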