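test_that("degenerate designs recover closed-form Poisson solutions", {
  # single stratum, intercept-only: rate = deaths/py, Var = 1/deaths
  one <- lifetable(data.frame(sex = "male", age = 70, year = 2000,
                              deaths = 25, person_years = 1000))
  m <- fit_poisson_rates(one, age_df = 0, year_df = 0)
  f <- m$fits[[1]]
  expect_equal(unname(exp(f$coef[1])), 25 / 1000, tolerance = 1e-10)
  expect_equal(unname(f$cov[1, 1]), 1 / 25, tolerance = 1e-8)
  u <- predict_underlying(m)
  expect_equal(u$data$deaths, 25, tolerance = 1e-9)

  # saturated design on a 2 (sex) x 2 (age) grid reproduces raw rates
  df <- expand.grid(sex = c("male", "female"), age = 70:71, year = 2000,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$person_years <- 1000
  df$deaths <- c(12, 7, 19, 11)
  lt <- lifetable(df)
  ms <- fit_poisson_rates(lt, age_df = 1, year_df = 0)
  us <- predict_underlying(ms)
  expect_equal(us$rate_array, lt$rate_array, tolerance = 1e-10)
})

test_that("covariance equals the brute-force inverse Fisher information", {
  lt <- varied_table()
  m <- fit_poisson_rates(lt, age_df = 2, year_df = 1)
  f <- m$fits[[1]]
  mu <- exp(drop(f$X %*% f$coef)) * lt$data$person_years
  info <- t(f$X) %*% (mu * f$X)
  brute <- solve(info)
  expect_equal(f$cov, brute, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("underlying rates are smooth predictions close to raw rates", {
  lt <- national_table()
  m <- fit_poisson_rates(lt)
  u <- predict_underlying(m)
  raw <- lt$data$deaths / lt$data$person_years
  sm <- u$data$deaths / u$data$person_years
  big <- lt$data$deaths > 200
  expect_true(any(big))
  expect_lt(median(abs(sm[big] / raw[big] - 1)), 0.1)
  # hand-computed linear predictor at one grid point
  f <- m$fits[[1]]
  i <- which(lt$data$sex == "female" & lt$data$age == 75 &
               lt$data$year == 2005)
  xrow <- f$X[i, , drop = FALSE]
  expect_equal(sm[i], unname(exp(drop(xrow %*% f$coef))), tolerance = 1e-12)
})

test_that("reducing table size leaves coefficients but scales covariance", {
  lt <- national_table()
  m1 <- fit_poisson_rates(lt)
  for (k in c(10, 200)) {
    mk <- fit_poisson_rates(reduce_size(lt, k))
    expect_equal(mk$fits[[1]]$coef, m1$fits[[1]]$coef, tolerance = 1e-6)
    expect_equal(mk$fits[[1]]$cov, k * m1$fits[[1]]$cov, tolerance = 1e-4)
  }
})

test_that("replicate draws reproduce the analytic coefficient spread", {
  lt <- national_table()
  m <- fit_poisson_rates(lt)
  reps <- draw_rate_replicates(m, 1000, seed = 31, keep_tables = FALSE)
  f <- m$fits[[1]]
  i <- which(m$table$data$sex == "male" & m$table$data$age == 80 &
               m$table$data$year == 2010)
  xrow <- f$X[i, , drop = FALSE]
  lr <- drop(xrow %*% reps$coef_draws[[1]])
  expect_equal(sd(lr), sqrt(drop(xrow %*% f$cov %*% t(xrow))),
               tolerance = 0.08)
  # mean centred on the fitted coefficient projection
  expect_equal(mean(lr), drop(xrow %*% f$coef), tolerance = 4 * sd(lr) / sqrt(1000))
  # reproducibility from the seed; different seed gives different draws
  reps2 <- draw_rate_replicates(m, 1000, seed = 31, keep_tables = FALSE)
  expect_identical(reps$coef_draws, reps2$coef_draws)
  reps3 <- draw_rate_replicates(m, 1000, seed = 32, keep_tables = FALSE)
  expect_false(identical(reps$coef_draws, reps3$coef_draws))
})

test_that("zero covariance collapses all replicates onto the underlying table", {
  lt <- varied_table()
  m <- fit_poisson_rates(lt, age_df = 2, year_df = 1)
  for (r in seq_along(m$fits)) m$fits[[r]]$cov[] <- 0
  reps <- draw_rate_replicates(m, 5, seed = 4)
  u <- predict_underlying(m)
  for (tab in reps$replicates)
    expect_equal(tab$rate_array, u$rate_array, tolerance = 1e-14)
  expect_error(draw_rate_replicates(m, 1, seed = 1), "at least 2")
})

test_that("replicate tables and materialisation agree", {
  lt <- varied_table()
  m <- fit_poisson_rates(lt, age_df = 2, year_df = 1)
  reps <- draw_rate_replicates(m, 3, seed = 11)
  lazy <- draw_rate_replicates(m, 3, seed = 11, keep_tables = FALSE)
  expect_null(lazy$replicates)
  expect_equal(replicate_table(lazy, 2)$rate_array,
               reps$replicates[[2]]$rate_array)
  # all replicate rates strictly positive (log-linear model)
  expect_true(all(reps$replicates[[1]]$rate_array > 0))
})

test_that("region-stratified tables get independent per-region fits", {
  p <- synth_params(py_total_per_year = 4e5, seed = 8)
  lt <- simulate_popmort(p, region_count = 2)
  m <- fit_poisson_rates(lt, age_df = 3, year_df = 2)
  expect_length(m$fits, 2L)
  u <- predict_underlying(m)
  # regional rates differ where the truth differs
  r1 <- lookup_rate(u, "male", 80.5, 2000.5, region = u$regions[1])
  r2 <- lookup_rate(u, "male", 80.5, 2000.5, region = u$regions[2])
  expect_false(isTRUE(all.equal(r1, r2)))
  reps <- draw_rate_replicates(m, 4, seed = 2, keep_tables = FALSE)
  expect_length(reps$coef_draws, 2L)
  expect_false(identical(reps$coef_draws[[1]], reps$coef_draws[[2]]))
})
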