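#' Configuration of the flexible parametric relative-survival model
#'
#' The model is specified on the log cumulative excess hazard scale,
#' \deqn{\ln \Lambda(t \mid Z_1) = s(\ln t \mid \gamma, k_0) + \beta Z_1,}
#' where \code{s} is a restricted cubic spline in log time.  Covariates
#' are age at diagnosis (as a restricted cubic spline) and sex; time-varying
#' effects are formed as interactions between a second restricted cubic
#' spline of log time and the covariate columns.
#'
#' @param baseline_df Degrees of freedom of the baseline log-time spline
#'   (default 5).
#' @param age_df Degrees of freedom of the age-at-diagnosis spline
#'   (default 4); 0 drops age from the model.
#' @param sex_effect Include a sex main effect (default TRUE).
#' @param tvc_df Degrees of freedom of the time-varying-effect spline
#'   (default 3); 0 drops all time-varying effects.
#' @param tvc_covariates Covariates given time-varying effects, a subset
#'   of \code{c("age", "sex")}; each interacts every one of its basis
#'   columns with the time-varying-effect spline.
#' @return An object of class \code{fpm_config}.
#' @export
fpm_config <- function(baseline_df = 5L, age_df = 4L, sex_effect = TRUE,
                       tvc_df = 3L, tvc_covariates = c("age", "sex")) {
  baseline_df <- as.integer(baseline_df)
  age_df <- as.integer(age_df)
  tvc_df <- as.integer(tvc_df)
  if (baseline_df < 1L) stop("baseline_df must be at least 1")
  if (age_df < 0L || tvc_df < 0L) stop("df values must be non-negative")
  tvc_covariates <- if (tvc_df > 0L) match.arg(tvc_covariates,
                                               c("age", "sex"),
                                               several.ok = TRUE)
                    else character(0)
  if ("age" %in% tvc_covariates && age_df == 0L)
    stop("time-varying effect of age requires age_df > 0")
  if ("sex" %in% tvc_covariates && !sex_effect)
    stop("time-varying effect of sex requires sex_effect = TRUE")
  structure(list(baseline_df = baseline_df, age_df = age_df,
                 sex_effect = sex_effect, tvc_df = tvc_df,
                 tvc_covariates = tvc_covariates),
            class = "fpm_config")
}

# Column layout of the coefficient vector: intercept; baseline spline;
# age spline; sex; tvc x age (time column varying slowest); tvc x sex.
fpm_layout <- function(config) {
  nm <- "(Intercept)"
  if (config$baseline_df > 0)
    nm <- c(nm, paste0("lnt", seq_len(config$baseline_df)))
  if (config$age_df > 0)
    nm <- c(nm, paste0("age", seq_len(config$age_df)))
  if (config$sex_effect) nm <- c(nm, "female")
  if ("age" %in% config$tvc_covariates)
    nm <- c(nm, paste0("tvc", rep(seq_len(config$tvc_df),
                                  each = config$age_df),
                       ":age", rep(seq_len(config$age_df), config$tvc_df)))
  if ("sex" %in% config$tvc_covariates)
    nm <- c(nm, paste0("tvc", seq_len(config$tvc_df), ":female"))
  nm
}

# Design matrix (and its log-time derivative) for given log times and
# covariates.  `specs` carries baseline_spec, age_spec, tvc_spec and the
# age rescaling range (age enters the spline on a [-1, 1] axis: raw-age
# truncated cubes crossed with time splines are numerically singular).
fpm_design <- function(config, specs, logt, age, female, deriv = FALSE) {
  n <- length(logt)
  if (!is.null(specs$age_tr)) age <- unit_scale(age, specs$age_tr)
  B <- rcs_basis(logt, specs$baseline_spec)
  A <- if (config$age_df > 0) rcs_basis(age, specs$age_spec) else NULL
  Tm <- if (config$tvc_df > 0) rcs_basis(logt, specs$tvc_spec) else NULL
  cols <- list(rep(1, n), B)
  if (config$age_df > 0) cols <- c(cols, list(A))
  if (config$sex_effect) cols <- c(cols, list(female))
  if ("age" %in% config$tvc_covariates)
    for (j in seq_len(config$tvc_df)) cols <- c(cols, list(A * Tm[, j]))
  if ("sex" %in% config$tvc_covariates)
    for (j in seq_len(config$tvc_df)) cols <- c(cols, list(female * Tm[, j]))
  X <- do.call(cbind, cols)
  colnames(X) <- fpm_layout(config)
  if (!deriv) return(list(X = X))
  Bd <- rcs_deriv(logt, specs$baseline_spec)
  Td <- if (config$tvc_df > 0) rcs_deriv(logt, specs$tvc_spec) else NULL
  dcols <- list(rep(0, n), Bd)
  if (config$age_df > 0) dcols <- c(dcols, list(A * 0))
  if (config$sex_effect) dcols <- c(dcols, list(rep(0, n)))
  if ("age" %in% config$tvc_covariates)
    for (j in seq_len(config$tvc_df)) dcols <- c(dcols, list(A * Td[, j]))
  if ("sex" %in% config$tvc_covariates)
    for (j in seq_len(config$tvc_df)) dcols <- c(dcols, list(female * Td[, j]))
  Xd <- do.call(cbind, dcols)
  list(X = X, Xd = Xd)
}

check_cohort <- function(cohort, need_region = FALSE) {
  req <- c("age_dx", "sex", "year_dx", "time", "event")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (need_region && !"region" %in% names(cohort))
    stop("life table is region-stratified; cohort needs a region column")
  if (any(cohort$time <= 0)) stop("follow-up time must be positive")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
  bad <- setdiff(unique(as.character(cohort$sex)), c("male", "female"))
  if (length(bad)) stop("unknown sex level(s): ", paste(bad, collapse = ", "))
  invisible(cohort)
}

#' Fit a flexible parametric relative-survival model
#'
#' Maximises the relative-survival likelihood
#' \deqn{\ell = \sum_i \left[ d_i \ln\{ h^*_i + \lambda(t_i \mid Z_{1i}) \}
#'   - \Lambda(t_i \mid Z_{1i}) \right],}
#' where \eqn{h^*_i} is the expected (general-population) mortality rate at
#' subject \code{i}'s attained age and calendar year at exit, looked up in
#' \code{table} (with region when the table is region-stratified),
#' \eqn{\Lambda = \exp(\eta)} is the cumulative excess hazard with
#' \eqn{\eta} the spline linear predictor in log time, and
#' \eqn{\lambda(t) = \Lambda(t)\, \eta'(\ln t) / t}.  The expected rates
#' are treated as fixed: all reported uncertainty comes from the cancer
#' cohort.  Region is never a model covariate — excess mortality is
#' assumed common across regions even when the expected rates differ by
#' region.
#'
#' Baseline and time-varying-effect knots are placed by [default_knots()]
#' on the log event (uncensored) times; age knots on the ages at diagnosis
#' of the full cohort.  Optimisation is quasi-Newton (BFGS) with the
#' analytic gradient; parameter points at which any event has
#' \eqn{h^* + \lambda \le 0} are assigned a large penalty so the line
#' search backs off (the likelihood is not defined there).  Unless
#' starting values are supplied, an exponential start is refined by an
#' all-cause fit (\eqn{h^* \equiv 0}) whose optimum seeds the excess
#' hazard fit.  The covariance is the inverse observed information
#' (finite differences of the analytic gradient).
#'
#' @param cohort Data frame with columns \code{age_dx}, \code{sex},
#'   \code{year_dx}, \code{time}, \code{event}, and \code{region} when
#'   \code{table} is region-stratified (\code{id} optional).
#' @param table A [lifetable()] of expected mortality rates, or
#'   \code{NULL} for an all-cause (no expected hazard) fit.
#' @param config An [fpm_config()].
#' @param init Optional starting coefficient vector (e.g. a previous fit
#'   on the same cohort with a perturbed rate table); skips the all-cause
#'   pre-fit.  Coefficients refer to specific knot locations, so supply
#'   \code{specs} alongside \code{init} when the data differ from those
#'   that produced it.
#' @param specs Optional spline specification to reuse (an [fit_fpm()]
#'   object or its \code{fpm_specs}); default: knots derived from this
#'   cohort.  Reusing specs keeps the design fixed across refits to
#'   resampled or perturbed data.
#' @param control List: \code{maxit} (default 1000), \code{gtol}
#'   (gradient sup-norm at convergence, default 1e-4; the Newton polish
#'   typically reaches ~1e-6) and \code{dtol} (Newton-decrement
#'   alternative criterion, default 1e-6).
#' @return An object of class \code{fpm}: coefficients, covariance,
#'   log-likelihood, spline specifications, configuration and data
#'   summaries.  Use [predict_rs()] and [lle_conditional()] for
#'   predictions.
#' @export
fit_fpm <- function(cohort, table, config = fpm_config(), init = NULL,
                    specs = NULL, control = list()) {
  stopifnot(inherits(config, "fpm_config"))
  ctrl <- utils::modifyList(list(maxit = 1000L, gtol = 1e-4, dtol = 1e-6),
                            control)
  need_region <- !is.null(table) && table$has_region
  check_cohort(cohort, need_region)
  n <- nrow(cohort)
  d <- as.numeric(cohort$event)
  if (sum(d) < 5) stop("too few events to fit the model")
  t_i <- as.numeric(cohort$time)
  female <- as.numeric(cohort$sex == "female")
  age <- as.numeric(cohort$age_dx)

  hstar <- if (is.null(table)) rep(0, n) else
    lookup_rate(table, cohort$sex, age + t_i, cohort$year_dx + t_i,
                if (need_region) cohort$region)

  if (is.null(specs)) {
    log_ev <- log(t_i[d == 1])
    age_tr <- if (config$age_df > 0) range(age)
    specs <- list(
      baseline_spec = default_knots(log_ev, config$baseline_df),
      age_spec = if (config$age_df > 0)
        default_knots(unit_scale(age, age_tr), config$age_df),
      tvc_spec = if (config$tvc_df > 0) default_knots(log_ev, config$tvc_df),
      age_tr = age_tr)
  } else {
    if (inherits(specs, "fpm")) specs <- fpm_specs(specs)
    stopifnot(inherits(specs$baseline_spec, "rcs_spec"))
  }
  des <- fpm_design(config, specs, log(t_i), age, female, deriv = TRUE)
  X <- des$X
  Xd <- des$Xd
  p <- ncol(X)
  ev <- d == 1

  negll <- function(theta, h) {
    eta <- drop(X %*% theta)
    etad <- drop(Xd %*% theta)
    Lam <- exp(eta)
    lam <- Lam * etad / t_i
    tot <- h + lam
    if (any(tot[ev] <= 0))
      return(1e10 + sum(pmax(-tot[ev], 0)))
    -(sum(log(tot[ev])) - sum(Lam))
  }
  neggr <- function(theta, h) {
    eta <- drop(X %*% theta)
    etad <- drop(Xd %*% theta)
    Lam <- exp(eta)
    lam <- Lam * etad / t_i
    tot <- h + lam
    if (any(tot[ev] <= 0)) return(rep(0, p))  # line search will reject
    w1 <- ifelse(ev, lam / tot, 0) - Lam
    w2 <- ifelse(ev, Lam / (t_i * tot), 0)
    -(drop(crossprod(X, w1)) + drop(crossprod(Xd, w2)))
  }

  if (is.null(init)) {
    theta0 <- numeric(p)
    theta0[1] <- log(sum(d) / sum(t_i))
    theta0[2] <- 1  # unit slope in ln t: exponential start
    ac <- stats::optim(theta0, negll, neggr, h = rep(0, n), method = "BFGS",
                       control = list(maxit = ctrl$maxit, reltol = 1e-12))
    init <- ac$par
  } else if (length(init) != p) {
    stop("init has wrong length: expected ", p)
  }
  par <- init
  val <- negll(par, hstar)
  grad <- neggr(par, hstar)
  if (val >= 1e9 || max(abs(grad)) >= ctrl$gtol) {
    opt <- stats::optim(init, negll, neggr, h = hstar, method = "BFGS",
                        control = list(maxit = ctrl$maxit, reltol = 1e-12))
    par <- opt$par
    val <- negll(par, hstar)
    grad <- neggr(par, hstar)
  }
  # Newton polish with the finite-difference Hessian of the analytic
  # gradient: BFGS curvature goes stale near the optimum and can leave
  # the score around 1e-2; a few damped Newton steps drive it down.
  # Besides the score sup-norm, convergence accepts a Newton decrement
  # g'H^{-1}g/2 below dtol — the expected log-likelihood gain of a full
  # Newton step, a scale-aware measure that is robust to the numerical
  # noise floor of objectives of magnitude 1e3-1e4.
  decrement <- Inf
  for (it in seq_len(25L)) {
    hess <- fd_jacobian(function(th) neggr(th, hstar), par)
    hess <- (hess + t(hess)) / 2
    step <- tryCatch(solve(hess, grad), error = function(e) grad)
    decrement <- sum(grad * step) / 2
    if (!is.finite(decrement) || decrement < 0) {
      step <- grad
      decrement <- sum(grad^2) / 2
    }
    if (max(abs(grad)) < ctrl$gtol || decrement < ctrl$dtol) break
    sc <- 1
    repeat {
      cand <- par - sc * step
      vc <- negll(cand, hstar)
      if (vc <= val || sc < 1e-8) break
      sc <- sc / 2
    }
    if (sc < 1e-8) break
    par <- cand
    val <- vc
    grad <- neggr(par, hstar)
  }
  converged <- val < 1e9 &&
    (max(abs(grad)) < ctrl$gtol || decrement < ctrl$dtol)
  opt <- list(par = par, value = val)
  cov <- tryCatch(solve(hess), error = function(e)
    stop("singular observed information: ", conditionMessage(e)))
  cov <- (cov + t(cov)) / 2

  # flag any interval of negative fitted excess hazard over follow-up
  tt <- exp(seq(min(log(t_i)), max(log(t_i)), length.out = 101))
  neg_haz <- FALSE
  for (prof_f in unique(female)) {
    dd <- fpm_design(config, specs, log(tt),
                     rep(stats::median(age), length(tt)),
                     rep(prof_f, length(tt)), deriv = TRUE)
    if (any(drop(dd$Xd %*% opt$par) < 0)) neg_haz <- TRUE
  }

  structure(list(
    coef = stats::setNames(opt$par, colnames(X)), cov = cov,
    loglik = -opt$value, converged = converged,
    max_score = max(abs(grad)), newton_decrement = decrement,
    baseline_spec = specs$baseline_spec, age_spec = specs$age_spec,
    tvc_spec = specs$tvc_spec, age_tr = specs$age_tr, config = config,
    n = n, n_events = sum(d),
    age_support = range(age), time_range = range(t_i),
    negative_excess_hazard = neg_haz),
    class = "fpm")
}

#' @export
print.fpm <- function(x, ...) {
  cat("Flexible parametric relative-survival model\n")
  cat("  n =", x$n, "subjects,", x$n_events, "events;",
      length(x$coef), "parameters\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  if (x$negative_excess_hazard)
    cat("  note: fitted excess hazard negative on part of follow-up\n")
  invisible(x)
}

# Jacobian of a vector function by central differences.
fd_jacobian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-6 * (1 + abs(x))
  J <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}

#' Relative-survival log-likelihood at arbitrary coefficients
#'
#' Evaluates \eqn{\ell(\theta) = \sum_i [ d_i \ln\{h^*_i +
#' \lambda(t_i)\} - \Lambda(t_i) ]} for a fitted model's spline
#' specification and data, at any coefficient vector (by default the
#' fitted one).  Useful for likelihood diagnostics and cross-checks.
#' Returns \code{NaN} when any event has non-positive total hazard at
#' \code{coef}.
#'
#' @param fit An [fit_fpm()] object.
#' @param cohort The cohort the model was fitted to.
#' @param table The life table the model was fitted against (NULL for
#'   an all-cause fit).
#' @param coef Coefficient vector (default: the fitted coefficients).
#' @return Scalar log-likelihood.
#' @export
fpm_loglik <- function(fit, cohort, table, coef = fit$coef) {
  stopifnot(inherits(fit, "fpm"))
  t_i <- as.numeric(cohort$time)
  d <- as.numeric(cohort$event)
  female <- as.numeric(as.character(cohort$sex) == "female")
  hstar <- if (is.null(table)) rep(0, length(t_i)) else
    lookup_rate(table, cohort$sex, cohort$age_dx + t_i,
                cohort$year_dx + t_i,
                if (table$has_region) cohort$region)
  des <- fpm_design(fit$config, fpm_specs(fit), log(t_i),
                    as.numeric(cohort$age_dx), female, deriv = TRUE)
  eta <- drop(des$X %*% coef)
  Lam <- exp(eta)
  lam <- Lam * drop(des$Xd %*% coef) / t_i
  sum(log((hstar + lam)[d == 1])) - sum(Lam)
}

fpm_specs <- function(fit) {
  list(baseline_spec = fit$baseline_spec, age_spec = fit$age_spec,
       tvc_spec = fit$tvc_spec, age_tr = fit$age_tr)
}

as_profile_df <- function(profile) {
  if (is.data.frame(profile)) return(profile)
  as.data.frame(profile[!vapply(profile, is.null, logical(1))],
                stringsAsFactors = FALSE)
}

z975 <- 1.959964

#' Predict relative survival for a covariate profile
#'
#' Computes \eqn{RS(t \mid Z_1) = \exp(-\exp(\eta))} with
#' \eqn{\eta = x'\hat\theta} the fitted log cumulative excess hazard, its
#' delta-method standard error \eqn{SE_{RS} = \Lambda \cdot RS \cdot
#' SE_\eta}, and a confidence interval obtained on the \eqn{\eta} scale
#' and back-transformed (hence always inside \[0, 1\] and asymmetric).
#' Times beyond the last baseline knot are extrapolated by the spline's
#' linear tail in log time.
#'
#' @param fit An [fit_fpm()] object.
#' @param profile List or one-row data frame with \code{age_dx} and
#'   \code{sex} (other fields are ignored by the excess-hazard model).
#' @param t Time(s) since diagnosis in years, positive; vectorised.
#' @return Data frame with columns \code{t}, \code{estimate}, \code{se},
#'   \code{ci_low}, \code{ci_high} on the relative-survival scale.
#' @export
predict_rs <- function(fit, profile, t) {
  stopifnot(inherits(fit, "fpm"), all(t > 0))
  pr <- as_profile_df(profile)
  if (fit$config$age_df > 0 &&
      (pr$age_dx[1] < fit$age_support[1] || pr$age_dx[1] > fit$age_support[2]))
    warning("profile age ", pr$age_dx[1],
            " outside fitted support [", fit$age_support[1], ", ",
            fit$age_support[2], "]")
  female <- as.numeric(as.character(pr$sex[1]) == "female")
  X <- fpm_design(fit$config, fpm_specs(fit), log(t),
                  rep(pr$age_dx[1], length(t)),
                  rep(female, length(t)))$X
  eta <- drop(X %*% fit$coef)
  se_eta <- sqrt(pmax(rowSums((X %*% fit$cov) * X), 0))
  Lam <- exp(eta)
  rs <- exp(-Lam)
  data.frame(t = t, estimate = rs, se = Lam * rs * se_eta,
             ci_low = exp(-exp(eta + z975 * se_eta)),
             ci_high = exp(-exp(eta - z975 * se_eta)))
}

#' Marginal (regression-standardised) relative survival
#'
#' Averages model-predicted relative survival at time \code{t} over the
#' empirical covariate distribution of the cohort:
#' \eqn{\widehat{RS}_m(t) = N^{-1} \sum_i \widehat{RS}_i(t \mid Z_{1i})}.
#' The delta-method standard error uses the averaged gradient
#' \eqn{N^{-1}\sum_i (-\Lambda_i RS_i) x_i}; the confidence interval is
#' symmetric on the natural scale (estimate ± 1.96 SE), truncated to
#' \[0, 1\].
#'
#' @param fit An [fit_fpm()] object.
#' @param cohort Data frame of subjects to standardise over (typically
#'   the fitting cohort).
#' @param t Single time since diagnosis in years.
#' @return One-row data frame with \code{t}, \code{estimate}, \code{se},
#'   \code{ci_low}, \code{ci_high}.
#' @export
predict_rs_marginal <- function(fit, cohort, t) {
  stopifnot(inherits(fit, "fpm"), length(t) == 1L, t > 0)
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort")
  female <- as.numeric(as.character(cohort$sex) == "female")
  X <- fpm_design(fit$config, fpm_specs(fit), rep(log(t), n),
                  as.numeric(cohort$age_dx), female)$X
  Lam <- exp(drop(X %*% fit$coef))
  rs <- exp(-Lam)
  g <- -drop(crossprod(X, Lam * rs)) / n
  se <- sqrt(max(drop(g %*% fit$cov %*% g), 0))
  est <- mean(rs)
  data.frame(t = t, estimate = est, se = se,
             ci_low = max(est - z975 * se, 0),
             ci_high = min(est + z975 * se, 1))
}
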