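test_that("simulated death counts are Poisson around the true surface", {
  p0 <- synth_params(py_total_per_year = 2e4, age_range = c(60, 62),
                     age_dx_range = c(60, 62), year_range = c(2000, 2001),
                     cohort_n = 50, seed = 1)
  truth <- true_rate_table(p0)
  sims <- vapply(1:400, function(s) {
    ps <- synth_params(py_total_per_year = 2e4, age_range = c(60, 62),
                       age_dx_range = c(60, 62), year_range = c(2000, 2001),
                       cohort_n = 50, seed = s)
    simulate_popmort(ps)$data$deaths
  }, numeric(12))
  lambda <- truth$data$deaths  # true mean = rate * py
  mu_hat <- rowMeans(sims)
  # empirical mean within 3 Monte-Carlo SDs of the Poisson mean
  expect_true(all(abs(mu_hat - lambda) <= 3 * sqrt(lambda / 400)))
  # dispersion index near 1 per stratum
  disp <- apply(sims, 1, var) / mu_hat
  expect_true(all(disp > 0.7 & disp < 1.4))
})

test_that("generated tables round-trip through the file format", {
  p <- synth_params(py_total_per_year = 3e5, seed = 6)
  lt <- simulate_popmort(p, region_count = 1)
  expect_false(lt$has_region)
  f <- tempfile(fileext = ".tsv")
  write_lifetable(lt, f)
  lt2 <- read_lifetable(f)
  expect_equal(lt2$rate_array, lt$rate_array)
  ltr <- simulate_popmort(p, region_count = 3)
  expect_true(ltr$has_region)
  write_lifetable(ltr, f)
  expect_equal(read_lifetable(f, has_region = TRUE)$rate_array,
               ltr$rate_array)
})

test_that("cohort generation respects its design and limits", {
  w <- small_world()
  ch <- w$cohort
  p <- w$params
  expect_equal(nrow(ch), p$cohort_n)
  expect_true(all(ch$time > 0))
  expect_true(all(ch$event %in% c(0, 1)))
  expect_true(all(ch$age_dx >= 50 & ch$age_dx <= 95))
  expect_true(all(ch$year_dx >= 2006 & ch$year_dx < 2007))
  # administrative censoring only: censored subjects exit at end of 2017
  cens <- ch[ch$event == 0, ]
  expect_equal(cens$year_dx + cens$time, rep(2018, nrow(cens)),
               tolerance = 1e-9)
  # immediate excess death in the scale -> 0 limit
  pfast <- synth_params(py_total_per_year = 5e5, cohort_n = 100,
                        excess_scale = 1e-6, seed = 2)
  chf <- simulate_cohort(pfast, true_rate_table(pfast))
  expect_lt(median(chf$time), 0.01)
  expect_equal(mean(chf$event), 1)
  # reproducibility from the seed
  ch2 <- simulate_cohort(p, w$truth)
  expect_identical(ch, ch2)
})

test_that("with no excess hazard the cohort tracks expected survival", {
  p <- synth_params(py_total_per_year = 5e5, cohort_n = 5000,
                    excess_scale = 1e9, seed = 33)
  truth <- true_rate_table(p)
  ch <- simulate_cohort(p, truth)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ch)
  tgrid <- c(2, 5, 8, 10)
  km <- summary(sf, times = tgrid)$surv
  Sbar <- rowMeans(vapply(seq_len(nrow(ch)), function(i)
    expected_survival(truth, ch[i, ], tgrid), numeric(4)))
  expect_true(all(abs(km - Sbar) < 3 * sqrt(Sbar * (1 - Sbar) / 5000) + 0.005))
})

test_that("true values reduce to closed forms in degenerate configurations", {
  # no excess: RS = 1, LLE = 0
  p0 <- synth_params(excess_scale = 1e9, seed = 1)
  tv0 <- true_values(p0, list(age_dx = 70, sex = "male", year_dx = 2006.5))
  expect_equal(tv0$rs, 1, tolerance = 1e-6)
  expect_equal(tv0$lle, 0, tolerance = 1e-4)

  # constant expected rate mu and exponential excess nu:
  # LLE = 1/mu - 1/(mu + nu)
  mu <- 0.05
  nu <- 0.05
  pc <- synth_params(pop_alpha = c(intercept = log(mu), age = 0,
                                   female = 0, year = 0),
                     excess_shape = 1, excess_scale = 1 / nu,
                     excess_beta_age = 0, excess_beta_female = 0,
                     seed = 1)
  tvc <- true_values(pc, list(age_dx = 70, sex = "female",
                              year_dx = 2006.5), horizon = 2000)
  expect_equal(tvc$le_p, 1 / mu, tolerance = 1e-6)
  expect_equal(tvc$lle, 1 / mu - 1 / (mu + nu), tolerance = 1e-4)

  # quadrature refinement is converged (the excess hazard's u^(a-1)
  # behaviour at u = 0 with shape < 1 caps the rate near the origin)
  p <- synth_params(seed = 1)
  pr <- list(age_dx = 65, sex = "male", year_dx = 2006.5)
  a <- true_values(p, pr, quad_nodes = 10)
  b <- true_values(p, pr, quad_nodes = 20)
  expect_lt(abs(a$lle - b$lle), 1e-6)
})

test_that("the rate model recovers the generator's truth coefficients", {
  hits <- 0L
  for (s in 1:10) {
    ps <- synth_params(py_total_per_year = 2e6, seed = 400 + s)
    lt <- simulate_popmort(ps)
    m <- fit_poisson_rates(lt, age_df = 1, year_df = 1)
    f <- m$fits[[1]]
    # the [-1,1] age axis rescales the true slope by (hi-lo)/2
    slope_true <- ps$pop_alpha[["age"]] * diff(f$age_tr) / 2
    ok_age <- abs(f$coef[["age1"]] - slope_true) <=
      3 * sqrt(f$cov["age1", "age1"])
    ok_sex <- abs(f$coef[["female"]] - ps$pop_alpha[["female"]]) <=
      3 * sqrt(f$cov["female", "female"])
    hits <- hits + (ok_age && ok_sex)
  }
  expect_gte(hits, 8L)
})
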