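#' Expected survival from a population life table
#'
#' Integrates the piecewise-constant expected hazard along a subject's
#' diagonal through the life table (attained age and attained calendar
#' year both advance with follow-up time) and returns
#' \eqn{S^*(t) = \exp(-\int_0^t h^*(u)\,du)}.  The integral is exact: the
#' hazard is constant within each band delimited by integer attained-age
#' and attained-year crossings, so the cumulative hazard is accumulated
#' band by band with no quadrature error.  Beyond the table's age or year
#' range the boundary rates persist (see [lookup_rate()]).
#'
#' @param table A [lifetable()].
#' @param profile List or one-row data frame with \code{age_dx},
#'   \code{sex}, \code{year_dx} and, for region-stratified tables,
#'   \code{region}.
#' @param t Non-decreasing vector of non-negative times (years since
#'   diagnosis).
#' @return Vector of survival probabilities in (0, 1], with
#'   \code{S*(0) = 1}.
#' @export
expected_survival <- function(table, profile, t) {
  stopifnot(inherits(table, "lifetable"), all(t >= 0), !is.unsorted(t))
  pr <- as_profile_df(profile)
  exp(-cum_expected_hazard(table, pr, t))
}

# Cumulative expected hazard at arbitrary times for a single profile.
cum_expected_hazard <- function(table, pr, t) {
  tmax <- max(t, 0)
  region <- if (table$has_region) pr$region[1]
  edges <- band_edges(pr$age_dx[1], pr$year_dx[1], tmax)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  r <- lookup_rate(table, pr$sex[1], pr$age_dx[1] + mid,
                   pr$year_dx[1] + mid, region)
  Hc <- c(0, cumsum(r * diff(edges)))
  b <- findInterval(t, edges, rightmost.closed = TRUE)
  b[b < 1] <- 1
  Hc[b] + r[pmin(b, length(r))] * (t - edges[b])
}

# Sorted band edges 0 = e_0 < ... < e_B = tmax at which attained age or
# attained calendar year crosses an integer.
band_edges <- function(age_dx, year_dx, tmax) {
  if (tmax <= 0) return(c(0, 0))
  k <- seq_len(ceiling(tmax) + 1)
  cand <- c(k - (age_dx %% 1), k - (year_dx %% 1))
  cand <- cand[cand > 0 & cand < tmax]
  sort(unique(c(0, cand, tmax)))
}

#' Life expectancy of the matched general population
#'
#' The area under expected survival, \eqn{LE_P = \int_0^{horizon}
#' S^*(u)\,du}, integrated exactly per constant-hazard band:
#' \eqn{\int} over a band of width \eqn{w} and rate \eqn{r} is
#' \eqn{S^*(e)\,(1 - e^{-rw})/r} (or \eqn{S^*(e)\,w} when \eqn{r = 0}).
#' Also reports the tail-mass bound \eqn{S^*(horizon) / r(horizon)}, an
#' upper bound on the life expectancy ignored by truncating at the
#' horizon when the boundary rate persists.
#'
#' @inheritParams expected_survival
#' @param horizon Positive truncation time in years.
#' @return List with \code{le_p}, \code{tail_bound} and
#'   \code{s_horizon} (\eqn{S^*} at the horizon).
#' @export
life_expectancy_pop <- function(table, profile, horizon) {
  stopifnot(inherits(table, "lifetable"), horizon > 0)
  pr <- as_profile_df(profile)
  region <- if (table$has_region) pr$region[1]
  edges <- band_edges(pr$age_dx[1], pr$year_dx[1], horizon)
  w <- diff(edges)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  r <- lookup_rate(table, pr$sex[1], pr$age_dx[1] + mid,
                   pr$year_dx[1] + mid, region)
  Hc <- c(0, cumsum(r * w))
  S0 <- exp(-Hc[-length(Hc)])
  piece <- ifelse(r > 0, (1 - exp(-r * w)) / r, w)
  s_h <- exp(-Hc[length(Hc)])
  r_h <- r[length(r)]
  if (r_h <= 0 && s_h > 1e-12)
    stop("zero expected rate at the horizon with non-negligible survivor ",
         "mass: life expectancy is unbounded under boundary clamping")
  list(le_p = sum(S0 * piece), tail_bound = if (r_h > 0) s_h / r_h else 0,
       s_horizon = s_h)
}

default_horizon <- function(age_dx) pmin(110 - age_dx, 80)

# Gauss-Legendre nodes/weights on [0, 1].
gl01 <- function(q) {
  g <- pracma::gaussLegendre(q, 0, 1)
  list(x = g$x, w = g$w)
}

#' @title Integration context for loss-in-life-expectancy evaluation
#'
#' @description
#' \code{lle_context()} precomputes everything about the quadrature grid
#' that does not depend on the rate table values or on the model
#' coefficients: per-subject band edges (integer attained-age and
#' attained-year crossings up to the horizon), life-table cell indices per
#' band, Gauss-Legendre node offsets and weights, and the spline time
#' bases evaluated at every node.  \code{lle_eval()} then evaluates
#' \eqn{LE_P}, \eqn{LE_C = \int RS \cdot S^*} and the analytic gradient of
#' LLE with respect to the model coefficients for any rate table on the
#' same grid and any coefficient vector — the workhorse of the replicate
#' loop, where only rates and coefficients change.
#'
#' The gradient is exact: \eqn{\partial RS(u)/\partial\theta =
#' -RS\,\Lambda\, x(u)}, so \eqn{\partial LLE/\partial\theta = \sum_u
#' w_u\, S^*(u)\, RS(u)\, \Lambda(u)\, x(u)}, accumulated without forming
#' the full node-level design matrix.
#'
#' @param fit An [fit_fpm()] object.
#' @param table A [lifetable()] (only its grid/stratification is used in
#'   the context; rates are supplied at evaluation time).
#' @param profiles Data frame of covariate profiles (\code{age_dx},
#'   \code{sex}, \code{year_dx}, optionally \code{region}).
#' @param horizon Scalar horizon in years, or \code{NULL} for the default
#'   per-subject rule \code{min(110 - age_dx, 80)}.
#' @param q Gauss-Legendre nodes per band.
#' @return An opaque context object for [lle_eval()].
#' @keywords internal
lle_context <- function(fit, table, profiles, horizon = NULL, q = 10L) {
  pr <- as_profile_df(profiles)
  n <- nrow(pr)
  age <- as.numeric(pr$age_dx)
  female <- as.numeric(as.character(pr$sex) == "female")
  H <- if (is.null(horizon)) default_horizon(age) else rep_len(horizon, n)
  if (any(H <= 0)) stop("non-positive integration horizon")
  Kmax <- ceiling(max(H)) + 1L
  k <- seq_len(Kmax)
  # candidate band edges, clamped into [0, H]; duplicates give zero-width
  # bands whose quadrature weight is zero
  cand <- cbind(outer(-(age %% 1), k, `+`),
                outer(-(as.numeric(pr$year_dx) %% 1), k, `+`))
  cand <- pmin(pmax(cand, 0), H)
  E <- cbind(0, t(apply(cand, 1L, sort)), H)
  nb <- ncol(E) - 1L
  W <- E[, -1L, drop = FALSE] - E[, -ncol(E), drop = FALSE]
  mid <- (E[, -1L, drop = FALSE] + E[, -ncol(E), drop = FALSE]) / 2
  sex_rep <- rep(as.character(pr$sex), nb)
  reg_rep <- if (table$has_region) rep(as.character(pr$region), nb)
  idx <- matrix(lifetable_cell_index(table, sex_rep, age + mid,
                                     as.numeric(pr$year_dx) + mid, reg_rep),
                n, nb)
  idx_end <- lifetable_cell_index(table, as.character(pr$sex), age + H,
                                  as.numeric(pr$year_dx) + H,
                                  if (table$has_region) pr$region)
  gl <- gl01(q)
  bx <- rep(seq_len(nb), each = q)
  du <- W[, bx, drop = FALSE] *
    rep(gl$x, times = nb)[col(W[, bx, drop = FALSE])]
  # du[i, (b-1)q + l] = W[i,b] * x_l ; node time u = E[i,b] + du
  u <- E[, bx, drop = FALSE] + du
  wgt <- W[, bx, drop = FALSE] *
    rep(gl$w, times = nb)[col(du)]
  lu <- log(pmax(u, 1e-12))
  cfg <- fit$config
  Bq <- rcs_basis(as.vector(lu), fit$baseline_spec)
  Bq <- lapply(seq_len(ncol(Bq)), function(j) matrix(Bq[, j], n))
  Tq <- if (cfg$tvc_df > 0) {
    Tm <- rcs_basis(as.vector(lu), fit$tvc_spec)
    lapply(seq_len(ncol(Tm)), function(j) matrix(Tm[, j], n))
  }
  A <- if (cfg$age_df > 0) rcs_basis(unit_scale(age, fit$age_tr),
                                     fit$age_spec)
  list(n = n, nb = nb, q = q, bx = bx, W = W, du = du, wgt = wgt,
       idx = idx, idx_end = idx_end, Bq = Bq, Tq = Tq, A = A,
       female = female, horizon = H, config = cfg)
}

# Split an FPM coefficient vector according to the design layout.
fpm_split_coef <- function(config, coef) {
  i <- 1L
  take <- function(m) {
    out <- coef[seq.int(i, length.out = m)]
    i <<- i + m
    out
  }
  b0 <- take(1L)
  gamma <- take(config$baseline_df)
  beta_age <- if (config$age_df > 0) take(config$age_df) else numeric(0)
  beta_sex <- if (config$sex_effect) take(1L) else 0
  theta_age <- if ("age" %in% config$tvc_covariates)
    matrix(take(config$tvc_df * config$age_df), config$age_df,
           config$tvc_df)  # column j = tvc basis j
  theta_sex <- if ("sex" %in% config$tvc_covariates) take(config$tvc_df)
  list(b0 = b0, gamma = gamma, beta_age = beta_age, beta_sex = beta_sex,
       theta_age = theta_age, theta_sex = theta_sex)
}

#' @rdname lle_context
#' @param ctx A context from [lle_context()].
#' @param rate_array Rate array of a [lifetable()] on the context's grid.
#' @param coef FPM coefficient vector.
#' @return For \code{lle_eval()}: list with per-profile vectors
#'   \code{le_p}, \code{le_c}, \code{lle}, \code{tail_bound}, and the
#'   gradient matrix \code{G} (profiles by coefficients) of LLE.
#' @keywords internal
lle_eval <- function(ctx, rate_array, coef) {
  cfg <- ctx$config
  R <- matrix(rate_array[ctx$idx], ctx$n, ctx$nb)
  Hband <- R * ctx$W
  Hc <- t(apply(Hband, 1L, cumsum))
  Hc0 <- cbind(0, Hc[, -ctx$nb, drop = FALSE])
  S0 <- exp(-Hc0)
  piece <- ifelse(R > 0, (1 - exp(-Hband)) / R, ctx$W)
  le_p <- rowSums(S0 * piece)
  tail_bound <- ifelse(rate_array[ctx$idx_end] > 0,
                       exp(-Hc[, ctx$nb]) / rate_array[ctx$idx_end], 0)

  # node-level expected survival and relative survival
  S <- exp(-(Hc0[, ctx$bx, drop = FALSE] + R[, ctx$bx, drop = FALSE] * ctx$du))
  sc <- fpm_split_coef(cfg, coef)
  eta <- sc$b0 + if (cfg$age_df > 0) drop(ctx$A %*% sc$beta_age) else 0
  eta <- eta + sc$beta_sex * ctx$female  # per-subject constant, recycled
  eta <- matrix(eta, ctx$n, ncol(ctx$du))
  for (j in seq_along(ctx$Bq)) eta <- eta + sc$gamma[j] * ctx$Bq[[j]]
  if (cfg$tvc_df > 0) {
    m <- matrix(0, ctx$n, cfg$tvc_df)
    if (!is.null(sc$theta_age)) m <- m + ctx$A %*% sc$theta_age
    if (!is.null(sc$theta_sex))
      m <- m + outer(ctx$female, sc$theta_sex)
    for (j in seq_len(cfg$tvc_df)) eta <- eta + m[, j] * ctx$Tq[[j]]
  }
  Lam <- exp(eta)
  RS <- exp(-Lam)
  intg <- ctx$wgt * RS * S
  intg[!is.finite(intg)] <- 0
  le_c <- rowSums(intg)

  v <- intg * Lam
  v[!is.finite(v)] <- 0
  s0 <- rowSums(v)
  p <- length(coef)
  G <- matrix(0, ctx$n, p)
  i <- 1L
  G[, i] <- s0; i <- i + 1L
  for (j in seq_along(ctx$Bq)) {
    G[, i] <- rowSums(v * ctx$Bq[[j]]); i <- i + 1L
  }
  if (cfg$age_df > 0) {
    G[, seq.int(i, length.out = cfg$age_df)] <- ctx$A * s0
    i <- i + cfg$age_df
  }
  if (cfg$sex_effect) {
    G[, i] <- ctx$female * s0; i <- i + 1L
  }
  if (cfg$tvc_df > 0) {
    sT <- lapply(ctx$Tq, function(Tj) rowSums(v * Tj))
    if ("age" %in% cfg$tvc_covariates)
      for (j in seq_len(cfg$tvc_df)) {
        G[, seq.int(i, length.out = cfg$age_df)] <- ctx$A * sT[[j]]
        i <- i + cfg$age_df
      }
    if ("sex" %in% cfg$tvc_covariates)
      for (j in seq_len(cfg$tvc_df)) {
        G[, i] <- ctx$female * sT[[j]]; i <- i + 1L
      }
  }
  list(le_p = le_p, le_c = le_c, lle = le_p - le_c,
       tail_bound = tail_bound, G = G)
}

lle_result <- function(le_p, le_c, se, horizon, quad_error, tail_bound) {
  structure(list(le_p = le_p, le_c = le_c, lle = le_p - le_c, se = se,
                 ci_low = le_p - le_c - z975 * se,
                 ci_high = le_p - le_c + z975 * se,
                 horizon = horizon, quad_error = quad_error,
                 tail_bound = tail_bound),
            class = "lle_result")
}

#' @export
print.lle_result <- function(x, ...) {
  cat(sprintf("LLE: %.3f years (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$lle, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  LE_pop %.3f, LE_cancer %.3f; horizon %.1f y (tail bound %.2g)\n",
              x$le_p, x$le_c, max(x$horizon), max(x$tail_bound)))
  invisible(x)
}

#' Conditional loss in life expectancy
#'
#' Loss in life expectancy for a single covariate profile,
#' \deqn{LLE = \int_0^{H} S^*(u)\,du - \int_0^{H} RS(u \mid Z_1)
#'   S^*(u \mid Z_2)\,du,}
#' where \eqn{S^*} comes from the life table (extrapolated by boundary
#' clamping), \eqn{RS} from the fitted model (extrapolated beyond
#' follow-up by the spline's linear tail in log time), and \eqn{H} is the
#' integration horizon.  \eqn{LE_P} is integrated exactly per band;
#' \eqn{LE_C} by composite Gauss-Legendre quadrature within each band
#' (the integrand is smooth inside bands, with kinks only at the
#' attained-age/year crossings).  When \code{refine} is \code{TRUE}, the
#' node count is doubled until the change in LLE is below \code{tol},
#' and the finest value is reported with the last change as
#' \code{quad_error}.
#'
#' The standard error is by the delta method over the model coefficients
#' only: the expected rates are treated as fixed, so \eqn{LE_P}
#' contributes no variance and \eqn{\partial LLE/\partial\theta} is the
#' (analytic) gradient of \eqn{-LE_C}.
#'
#' @param fit An [fit_fpm()] object.
#' @param table A [lifetable()].
#' @param profile Covariate profile (list or one-row data frame) with
#'   \code{age_dx}, \code{sex}, \code{year_dx}, optionally \code{region}.
#' @param horizon Scalar horizon in years; \code{NULL} (default) uses
#'   \code{min(110 - age_dx, 80)}.
#' @param quad_nodes Gauss-Legendre nodes per band (default 10).
#' @param refine Double the node count until converged (default TRUE).
#' @param tol Convergence tolerance in years for refinement.
#' @param max_doublings Refinement cap; exceeding it is an error.
#' @return An object of class \code{lle_result} with \code{le_p},
#'   \code{le_c}, \code{lle}, \code{se}, confidence limits, horizon,
#'   quadrature error estimate and tail bound.
#' @export
lle_conditional <- function(fit, table, profile, horizon = NULL,
                            quad_nodes = 10L, refine = TRUE, tol = 1e-6,
                            max_doublings = 4L) {
  stopifnot(inherits(fit, "fpm"), inherits(table, "lifetable"))
  pr <- as_profile_df(profile)[1, , drop = FALSE]
  q <- as.integer(quad_nodes)
  ctx <- lle_context(fit, table, pr, horizon, q)
  ev <- lle_eval(ctx, table$rate_array, fit$coef)
  quad_error <- NA_real_
  if (refine) {
    for (dd in seq_len(max_doublings)) {
      q <- 2L * q
      ctx2 <- lle_context(fit, table, pr, horizon, q)
      ev2 <- lle_eval(ctx2, table$rate_array, fit$coef)
      quad_error <- abs(ev2$lle - ev$lle)
      ev <- ev2
      if (quad_error < tol) break
    }
    if (quad_error >= tol)
      stop("LLE quadrature did not converge to ", tol, " years within ",
           max_doublings, " doublings (last change ", quad_error, ")")
  }
  g <- drop(ev$G)
  se <- sqrt(max(drop(g %*% fit$cov %*% g), 0))
  lle_result(ev$le_p, ev$le_c, se, ctx$horizon, quad_error, ev$tail_bound)
}

#' Marginal (regression-standardised) loss in life expectancy
#'
#' Averages the conditional LLE over the cohort's empirical covariate
#' distribution, \eqn{\widehat{LLE}_m = N^{-1} \sum_i
#' \widehat{LLE}_i(Z_i)}, with delta-method standard error based on the
#' averaged per-subject gradient.  Each subject's LLE uses the same band
#' structure, horizon rule and quadrature as [lle_conditional()] (without
#' refinement), so the marginal estimate equals the arithmetic mean of
#' the per-subject conditional estimates by construction.
#'
#' @inheritParams lle_conditional
#' @param cohort Data frame of subjects (profile columns as in
#'   [lle_conditional()]).
#' @return An \code{lle_result}; additionally carries the per-subject
#'   estimates as attribute \code{"per_subject"}.
#' @export
lle_marginal <- function(fit, table, cohort, horizon = NULL,
                         quad_nodes = 10L) {
  stopifnot(inherits(fit, "fpm"), inherits(table, "lifetable"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  ctx <- lle_context(fit, table, cohort, horizon, as.integer(quad_nodes))
  ev <- lle_eval(ctx, table$rate_array, fit$coef)
  g <- colMeans(ev$G)
  se <- sqrt(max(drop(g %*% fit$cov %*% g), 0))
  out <- lle_result(mean(ev$le_p), mean(ev$le_c), se, ctx$horizon,
                    NA_real_, max(ev$tail_bound))
  attr(out, "per_subject") <- ev$lle
  out
}
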