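test_that("Rubin's rules reproduce the hand-computed example", {
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1), se_conventional = 1)
  expect_equal(p$mean, 2)
  expect_equal(p$v_within, 1)
  expect_equal(p$v_between, 1)
  expect_equal(p$v_pooled, 7 / 3)
  expect_equal(p$se_pooled, sqrt(7 / 3))
  # identity V_p = V_W + V_B + V_B/M, exactly
  expect_identical(p$v_pooled, p$v_within + p$v_between + p$v_between / p$M)
})

test_that("degenerate and boundary pooling cases behave", {
  # identical replicates: no between-variance
  p <- pool_rubin(rep(4.2, 10), rep(0.3, 10), se_conventional = 0.3)
  expect_equal(p$v_between, 0)
  expect_equal(p$v_pooled, p$v_within)
  expect_equal(p$se_pooled, sqrt(p$v_within))
  expect_equal(p$rp, 0)
  # se_conv = se_pooled / sqrt(2)  =>  RP = 100
  q <- pool_rubin(c(1, 2, 3), c(1, 1, 1), sqrt(7 / 3) / sqrt(2))
  expect_equal(q$rp, 100)
  # negative RP is representable
  r <- pool_rubin(rep(1, 5), rep(0.1, 5), se_conventional = 0.2)
  expect_lt(r$rp, 0)
  # pooling is invariant to replicate order
  set.seed(5)
  est <- rnorm(20)
  ses <- runif(20, 0.5, 1)
  o <- sample(20)
  a <- pool_rubin(est, ses, 1)
  b <- pool_rubin(est[o], ses[o], 1)
  expect_equal(a$v_pooled, b$v_pooled)
  expect_error(pool_rubin(1, 1, 1), "at least 2")
  expect_error(pool_rubin(c(1, 2), c(1, 1), 0), "positive")
  expect_error(pool_rubin(c(1, 2), c(-1, 1), 1), "non-negative")
})

test_that("scenario specifications encode the study grid consistently", {
  a <- scenario_spec("A")
  expect_equal(a$popmort_factor, 1)
  expect_false(a$region_stratified)
  expect_equal(a$setting, "1")
  j <- scenario_spec("J", M = 50, seed = 3)
  expect_equal(j$cohort_fraction, 0.1)
  expect_equal(j$popmort_factor, 10)
  expect_true(j$region_stratified)
  expect_equal(j$setting, "2S")
  expect_error(scenario_spec("D", popmort_factor = 10), "2000")
  expect_error(scenario_spec("Z"))
})

test_that("zeroed rate covariance degenerates the pipeline to conventional", {
  w <- small_world()
  lt <- fixture("small_popmort", {
    simulate_popmort(synth_params(py_total_per_year = 5e5, seed = 42))
  })
  rep0 <- run_scenario(w$cohort, lt, scenario_spec("A", M = 10, seed = 2),
                       config = fpm_config(baseline_df = 3, age_df = 2,
                                           tvc_df = 2,
                                           tvc_covariates = "sex"),
                       zero_rate_cov = TRUE)
  expect_equal(rep0$results$rp, rep(0, nrow(rep0$results)),
               tolerance = 1e-8)
  expect_equal(rep0$results$pool_est, rep0$results$conv_est,
               tolerance = 1e-8)
  expect_equal(rep0$M_effective, 10L)
})

test_that("a small scenario run produces a coherent report", {
  w <- small_world()
  lt <- fixture("small_popmort", {
    simulate_popmort(synth_params(py_total_per_year = 5e5, seed = 42))
  })
  rep1 <- fixture("scenario_small_C", {
    run_scenario(w$cohort, lt, scenario_spec("C", M = 30, seed = 2),
                 config = fpm_config(baseline_df = 3, age_df = 2,
                                     tvc_df = 2, tvc_covariates = "sex"))
  })
  res <- rep1$results
  expect_equal(nrow(res), 18L)  # (8 profiles + marginal) x 2 measures
  expect_true(all(res$conv_se > 0))
  expect_true(all(res$pool_se > 0))
  expect_true(all(res$v_pooled >= res$v_within - 1e-12))
  expect_true(all(res$conv_lci <= res$conv_est & res$conv_est <= res$conv_uci))
  rs <- res[res$measure == "rs5", ]
  expect_true(all(rs$conv_est >= 0 & rs$conv_est <= 1))
  expect_true(all(rs$pool_lci >= 0 & rs$pool_uci <= 1))
  # identity rp = 100 ((se_pool/se_conv)^2 - 1) on reported columns
  expect_equal(res$rp, 100 * ((res$pool_se / res$conv_se)^2 - 1),
               tolerance = 1e-10)
})

test_that("report tables assemble, serialise and round-trip", {
  rep1 <- fixture("scenario_small_C", {
    w <- small_world()
    lt <- fixture("small_popmort", {
      simulate_popmort(synth_params(py_total_per_year = 5e5, seed = 42))
    })
    run_scenario(w$cohort, lt, scenario_spec("C", M = 30, seed = 2),
                 config = fpm_config(baseline_df = 3, age_df = 2,
                                     tvc_df = 2, tvc_covariates = "sex"))
  })
  tab <- report_table(rep1)
  expect_equal(sort(unique(tab$method)), c("bootstrap", "conventional"))
  # the conventional rows compare the method with itself: RP identically 0
  expect_true(all(tab$rp[tab$method == "conventional"] == 0))
  f <- tempfile(fileext = ".csv")
  write_report_table(tab, f, digits = 6)
  back <- read_report_table(f)
  expect_equal(back$estimate, signif(tab$estimate, 6))
  expect_equal(back$rp, signif(tab$rp, 6))
  expect_equal(nrow(back), nrow(tab))
})
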