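#' @title Poisson spline smoothing of population mortality rates
#'
#' @description
#' Fits a Poisson regression of death counts on sex, a restricted cubic
#' spline of age, a restricted cubic spline of calendar year, and all
#' pairwise interactions (sex with each age basis column, sex with each
#' year basis column, and the full tensor of age and year basis columns),
#' with log person-years as offset.  When the table is region-stratified,
#' a separate model is fitted to each region.  The fitted model supplies
#' both the underlying (smoothed) expected mortality rates used in place
#' of the raw table, and — through multivariate-normal draws of the
#' coefficient vector — replicate rate tables embodying the sampling
#' uncertainty of the rates.
#'
#' Fractional death counts (produced by [reduce_size()]) are fitted by the
#' same Poisson score equations.  Because dividing deaths and person-years
#' by a factor \code{k} leaves every rate unchanged, the fitted
#' coefficients are identical across sizes while the covariance matrix
#' scales by \code{k}.
#'
#' @param table A [lifetable()].
#' @param age_df Degrees of freedom for the age spline (default 5).
#' @param year_df Degrees of freedom for the calendar-year spline
#'   (default 3).
#' @return An object of class \code{rate_model}: a list with per-region
#'   fits (\code{coef}, \code{cov}, \code{age_spec}, \code{year_spec},
#'   design matrix and row map), the source table, and a design
#'   description.
#' @seealso [predict_underlying()], [draw_rate_replicates()]
#' @export
fit_poisson_rates <- function(table, age_df = 5L, year_df = 3L) {
  stopifnot(inherits(table, "lifetable"))
  regions <- if (table$has_region) table$regions else NA_character_
  fits <- lapply(regions, function(rg) {
    rows <- if (table$has_region) which(table$data$region == rg)
            else seq_len(nrow(table$data))
    d <- table$data[rows, , drop = FALSE]
    # map age and year onto [-1, 1] before knot placement: the tensor of
    # raw truncated cubes over an 80-year age range by 40-year period
    # range is numerically singular, the affine rescaling is lossless
    age_tr <- range(d$age)
    year_tr <- range(d$year)
    age_spec <- if (age_df > 0)
      default_knots(unit_scale(d$age, age_tr), age_df,
                    weights = d$person_years)
    year_spec <- if (year_df > 0)
      default_knots(unit_scale(d$year, year_tr), year_df,
                    weights = d$person_years)
    X <- poisson_design(d$sex, unit_scale(d$age, age_tr),
                        unit_scale(d$year, year_tr), age_spec, year_spec,
                        two_sexes = length(table$sexes) > 1L)
    fit <- suppressWarnings(stats::glm.fit(
      X, d$deaths, family = stats::poisson(),
      offset = log(d$person_years),
      control = list(maxit = 100, epsilon = 1e-10)))
    if (!fit$converged)
      stop("Poisson rate model did not converge",
           if (table$has_region) paste0(" (region ", rg, ")"))
    mu <- fit$fitted.values
    info <- crossprod(X * sqrt(mu))
    cov <- tryCatch(solve(info), error = function(e)
      stop("singular information in Poisson rate model: ",
           conditionMessage(e)))
    cov <- (cov + t(cov)) / 2
    list(region = if (table$has_region) rg else NULL,
         coef = fit$coefficients, cov = cov,
         age_spec = age_spec, year_spec = year_spec,
         age_tr = age_tr, year_tr = year_tr,
         X = X, rows = rows, converged = fit$converged,
         deviance = fit$deviance)
  })
  names(fits) <- if (table$has_region) table$regions else "all"
  structure(list(
    fits = fits, table = table, age_df = age_df, year_df = year_df,
    design_description = paste(
      "sex + rcs(age) + rcs(year) + sex:rcs(age) + sex:rcs(year)",
      "+ rcs(age):rcs(year), offset log(person_years)")),
    class = "rate_model")
}

unit_scale <- function(v, tr) (2 * v - tr[1] - tr[2]) / (tr[2] - tr[1])

# Design matrix for the rate model: intercept, female indicator, age and
# year spline bases, and all pairwise interactions.  `age` and `year`
# are expected on the rescaled ([-1, 1]) axis matching the knot specs;
# terms drop out when a spec is NULL (df 0) or only one sex is present.
poisson_design <- function(sex, age, year, age_spec, year_spec,
                           two_sexes = TRUE) {
  female <- as.numeric(sex == "female")
  A <- if (!is.null(age_spec)) rcs_basis(age, age_spec)
  Y <- if (!is.null(year_spec)) rcs_basis(year, year_spec)
  cols <- list("(Intercept)" = rep(1, length(sex)))
  add <- function(cols, block, names) {
    colnames(block) <- names
    c(cols, list(block))
  }
  if (two_sexes) cols <- add(cols, cbind(female), "female")
  if (!is.null(A))
    cols <- add(cols, A, paste0("age", seq_len(ncol(A))))
  if (two_sexes && !is.null(A))
    cols <- add(cols, female * A, paste0("female:age", seq_len(ncol(A))))
  if (!is.null(Y))
    cols <- add(cols, Y, paste0("year", seq_len(ncol(Y))))
  if (two_sexes && !is.null(Y))
    cols <- add(cols, female * Y, paste0("female:year", seq_len(ncol(Y))))
  if (!is.null(A) && !is.null(Y)) {
    AY <- matrix(0, length(age), ncol(A) * ncol(Y))
    for (j in seq_len(ncol(Y)))
      AY[, (j - 1L) * ncol(A) + seq_len(ncol(A))] <- A * Y[, j]
    cols <- add(cols, AY,
                paste0("age", rep(seq_len(ncol(A)), ncol(Y)), ":year",
                       rep(seq_len(ncol(Y)), each = ncol(A))))
  }
  nm <- unlist(lapply(cols, function(b)
    if (is.null(colnames(b))) "(Intercept)" else colnames(b)))
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Poisson mortality rate model:",
      length(x$fits), if (length(x$fits) > 1) "regional fits" else "fit", "\n")
  cat("  design:", x$design_description, "\n")
  cat("  age df:", x$age_df, "; year df:", x$year_df,
      "; parameters per fit:", length(x$fits[[1]]$coef), "\n")
  invisible(x)
}

# Clone a life table with new rates on the identical grid, skipping
# re-validation.  deaths is kept consistent as rate * person_years
# (bookkeeping only; downstream code uses rates).
lifetable_with_rates <- function(template, rates) {
  stopifnot(length(rates) == nrow(template$data))
  out <- template
  out$data$deaths <- rates * out$data$person_years
  arr <- template$rate_array
  arr[template$cell_index] <- rates
  out$rate_array <- arr
  out
}

#' Underlying (smoothed) expected mortality rates
#'
#' Evaluates the fitted Poisson model over the source table's grid and
#' returns a rate-bearing life table with \code{rate = exp(linear
#' predictor)} in every cell.  These smoothed rates stand in for the raw
#' rates as the "fixed" expected mortality of the conventional analysis,
#' so that conventional and replicate-based analyses differ only in
#' whether coefficient uncertainty is propagated.
#'
#' @param model A [fit_poisson_rates()] fit.
#' @return A [lifetable()] on the same grid with smoothed rates
#'   (\code{deaths} set to \code{rate * person_years} for bookkeeping).
#' @export
predict_underlying <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  rates <- numeric(nrow(model$table$data))
  for (f in model$fits)
    rates[f$rows] <- exp(drop(f$X %*% f$coef))
  lifetable_with_rates(model$table, rates)
}

#' Parametric-bootstrap replicate rate tables
#'
#' Draws \code{M} coefficient vectors from the multivariate normal
#' distribution \eqn{N(\hat\beta, \hat\Sigma)} of the fitted Poisson rate
#' model (independently per region for region-stratified tables) and
#' converts each draw to a full replicate life table with
#' \code{rate = exp(linear predictor)}.  The covariance is factorised by a
#' symmetric eigendecomposition with negative eigenvalues clipped at zero;
#' if the decomposition fails, a jitter of \code{1e-10 * trace} is added
#' to the diagonal once before giving up.
#'
#' Reproducibility: replicate draws for region \code{r} use a
#' deterministic child seed derived from \code{(seed, r)}, so per-region
#' streams are independent and the full set is reproducible from the
#' single master seed.
#'
#' @param model A [fit_poisson_rates()] fit.
#' @param M Number of replicates, at least 2.
#' @param seed Master integer seed.
#' @param keep_tables Materialise the \code{M} replicate life tables
#'   (default).  \code{FALSE} keeps only the coefficient draws — enough
#'   for rate-level diagnostics at a fraction of the memory; tables can
#'   be rebuilt on demand with [replicate_table()].
#' @return An object of class \code{rate_replicates}: list with
#'   \code{replicates} (list of \code{M} [lifetable()]s, or \code{NULL}
#'   when \code{keep_tables = FALSE}), \code{M}, \code{seed}, and the
#'   coefficient draws per region.
#' @export
draw_rate_replicates <- function(model, M, seed, keep_tables = TRUE) {
  stopifnot(inherits(model, "rate_model"))
  M <- as.integer(M)
  if (M < 2L) stop("M must be at least 2")
  draws <- vector("list", length(model$fits))
  names(draws) <- names(model$fits)
  for (r in seq_along(model$fits)) {
    f <- model$fits[[r]]
    draws[[r]] <- rmvn_eigen(M, f$coef, f$cov, child_seed(seed, r))
  }
  out <- structure(list(replicates = NULL, M = M, seed = seed,
                        coef_draws = draws, model = model),
                   class = "rate_replicates")
  if (keep_tables)
    out$replicates <- lapply(seq_len(M), function(m) replicate_table(out, m))
  out
}

#' Rebuild one replicate life table from its coefficient draw
#'
#' @param reps A [draw_rate_replicates()] object.
#' @param m Replicate index in 1..M.
#' @return A [lifetable()].
#' @export
replicate_table <- function(reps, m) {
  stopifnot(inherits(reps, "rate_replicates"), m >= 1, m <= reps$M)
  model <- reps$model
  rates <- numeric(nrow(model$table$data))
  for (r in seq_along(model$fits)) {
    f <- model$fits[[r]]
    rates[f$rows] <- exp(drop(f$X %*% reps$coef_draws[[r]][, m]))
  }
  lifetable_with_rates(model$table, rates)
}

#' @export
print.rate_replicates <- function(x, ...) {
  cat("Replicate rate tables: M =", x$M, ", seed =", x$seed, "\n")
  invisible(x)
}

# Multivariate normal draws via symmetric eigendecomposition with
# negative eigenvalues clipped at 0; returns a p x M matrix.
rmvn_eigen <- function(M, mean, cov, seed) {
  p <- length(mean)
  e <- tryCatch(eigen(cov, symmetric = TRUE), error = function(err) {
    eigen(cov + diag(1e-10 * sum(diag(cov)), p), symmetric = TRUE)
  })
  lam <- pmax(e$values, 0)
  fac <- e$vectors %*% (sqrt(lam) * t(e$vectors))  # symmetric square root
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  Z <- matrix(stats::rnorm(p * M), p, M)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  mean + fac %*% Z
}

# Deterministic child seed below 2^31, mixing a master seed with integer
# keys; double arithmetic keeps intermediates exact (< 2^53).
child_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in keys)
    s <- (s * 48271 + as.numeric(k) * 9973 + 12345) %% 2147483647
  as.integer(s)
}
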