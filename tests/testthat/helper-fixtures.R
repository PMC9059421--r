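# Memoised fixtures: expensive synthetic worlds and fits are built once
# per test run and shared across files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Life table with one constant rate everywhere (wide age/year support).
flat_table <- function(rate, age_range = c(30, 105),
                       year_range = c(1995, 2040), py = 1000) {
  df <- expand.grid(sex = c("male", "female"),
                    age = seq(age_range[1], age_range[2]),
                    year = seq(year_range[1], year_range[2]),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$person_years <- py
  df$deaths <- rate * py
  lifetable(df)
}

# A small non-flat life table for lookup / reduction tests.
varied_table <- function() {
  df <- expand.grid(sex = c("male", "female"), age = 50:60,
                    year = 2000:2005, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$person_years <- 500 + 10 * (df$age - 50)
  df$deaths <- 2 + (df$age %% 7) + 0.5 * (df$year %% 3) +
    0.3 * (df$sex == "female")
  lifetable(df)
}

# Mid-sized synthetic world: enough events for a stable FPM fit, small
# enough for second-scale tests.
small_world <- function() {
  fixture("small_world", {
    p <- synth_params(py_total_per_year = 5e5, cohort_n = 600, seed = 42)
    truth <- true_rate_table(p)
    cohort <- simulate_cohort(p, truth)
    list(params = p, truth = truth, cohort = cohort)
  })
}

small_fit <- function() {
  fixture("small_fit", {
    w <- small_world()
    fit_fpm(w$cohort, w$truth, fpm_config())
  })
}

# Study-scale world: national life table (sex x 18-99 x 1975-2017,
# ~9M person-years/year) and a cohort of 3400 diagnosed in 2006.
full_world <- function() {
  fixture("full_world", {
    p <- synth_params(seed = 1706)
    truth <- true_rate_table(p)
    list(params = p, truth = truth,
         popmort = simulate_popmort(p),
         cohort = simulate_cohort(p, truth))
  })
}

national_table <- function() full_world()$popmort

# Per-subject brute-force relative-survival log-likelihood, assembled
# from scalar spline evaluations (independent of the fitter's design and
# likelihood code paths).
brute_loglik <- function(fit, ch, table, theta) {
  total <- 0
  for (i in seq_len(nrow(ch))) {
    u <- log(ch$time[i])
    f <- as.numeric(ch$sex[i] == "female")
    as <- (2 * ch$age_dx[i] - sum(fit$age_tr)) / diff(fit$age_tr)
    B <- drop(rcs_basis(u, fit$baseline_spec))
    Bd <- drop(rcs_deriv(u, fit$baseline_spec))
    A <- drop(rcs_basis(as, fit$age_spec))
    Tb <- drop(rcs_basis(u, fit$tvc_spec))
    Td <- drop(rcs_deriv(u, fit$tvc_spec))
    x <- c(1, B, A, f, as.vector(outer(A, Tb)), f * Tb)
    xd <- c(0, Bd, 0 * A, 0, as.vector(outer(A, Td)), f * Td)
    eta <- sum(x * theta)
    Lam <- exp(eta)
    lam <- Lam * sum(xd * theta) / ch$time[i]
    h <- lookup_rate(table, ch$sex[i], ch$age_dx[i] + ch$time[i],
                     ch$year_dx[i] + ch$time[i],
                     if (table$has_region) ch$region[i])
    if (ch$event[i] == 1) total <- total + log(h + lam)
    total <- total - Lam
  }
  total
}

# A hand-built "fit" whose relative survival is exactly exp(-nu * t):
# baseline df 1 with unit slope in ln t makes ln Lambda = ln(nu) + ln t.
exponential_rs_fit <- function(nu, se_scale = 1e-4) {
  cfg <- fpm_config(baseline_df = 1, age_df = 0, sex_effect = FALSE,
                    tvc_df = 0)
  structure(list(coef = c("(Intercept)" = log(nu), lnt1 = 1),
                 cov = diag(se_scale^2, 2), loglik = NA_real_,
                 converged = TRUE, max_score = 0,
                 baseline_spec = rcs_spec(c(-20, 20)), age_spec = NULL,
                 tvc_spec = NULL, age_tr = NULL, config = cfg,
                 n = 0L, n_events = 0L, age_support = c(0, 0),
                 time_range = c(1e-8, 20),
                 negative_excess_hazard = FALSE),
            class = "fpm")
}
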