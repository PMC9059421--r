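#' Pool replicate estimates with Rubin's rules
#'
#' Given \code{M} replicate estimates \eqn{\hat\theta_m} with standard
#' errors \eqn{SE_m} (one per replicate rate table), computes the pooled
#' mean \eqn{\bar\theta = M^{-1}\sum \hat\theta_m}, the within-replicate
#' variance \eqn{V_W = M^{-1}\sum SE_m^2}, the between-replicate variance
#' \eqn{V_B = (M-1)^{-1}\sum (\hat\theta_m - \bar\theta)^2}, the pooled
#' variance \eqn{V_p = V_W + V_B + V_B / M}, and the relative \% precision
#' against the conventional (fixed-rates) analysis,
#' \deqn{RP = 100\,\{(SE_{pool} / SE_{conv})^2 - 1\}.}
#' RP can be slightly negative: \eqn{V_p \ge V_W} always holds, but
#' \eqn{SE_{conv}} is the conventional model's own standard error, not
#' \eqn{\sqrt{V_W}}, so sampling noise can push the ratio below 1 when
#' rate uncertainty is negligible.
#'
#' Pooling is on the natural scale of the measure (proportion for
#' relative survival, years for loss in life expectancy), matching how
#' the variance components are defined.
#'
#' @param estimates Numeric vector of M replicate point estimates.
#' @param ses Numeric vector of M replicate standard errors (>= 0).
#' @param se_conventional Conventional standard error (> 0).
#' @return An object of class \code{pooled_estimate}: \code{M},
#'   \code{mean}, \code{v_within}, \code{v_between}, \code{v_pooled},
#'   \code{se_pooled}, \code{se_conventional}, \code{rp}.
#' @export
pool_rubin <- function(estimates, ses, se_conventional) {
  M <- length(estimates)
  if (M < 2L) stop("Rubin's rules need at least 2 replicates")
  if (length(ses) != M) stop("estimates and ses must have equal length")
  if (any(ses < 0)) stop("standard errors must be non-negative")
  if (!is.numeric(se_conventional) || se_conventional <= 0)
    stop("se_conventional must be positive")
  m <- mean(estimates)
  v_w <- mean(ses^2)
  v_b <- sum((estimates - m)^2) / (M - 1)
  v_p <- v_w + v_b + v_b / M
  se_p <- sqrt(v_p)
  structure(list(M = M, mean = m, v_within = v_w, v_between = v_b,
                 v_pooled = v_p, se_pooled = se_p,
                 se_conventional = se_conventional,
                 rp = 100 * ((se_p / se_conventional)^2 - 1)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled over M = %d replicates: %.4f (SE %.4g)\n",
              x$M, x$mean, x$se_pooled))
  cat(sprintf("  V_W %.4g + V_B %.4g + V_B/M = V_p %.4g; conventional SE %.4g; RP %.2f%%\n",
              x$v_within, x$v_between, x$v_pooled, x$se_conventional, x$rp))
  invisible(x)
}

scenario_grid <- data.frame(
  label = LETTERS[1:10],
  cohort_fraction = c(1, 1, 1, 1, 0.1, 1, 1, 1, 1, 0.1),
  popmort_factor = c(1, 10, 200, 2000, 10, 1, 10, 200, 2000, 10),
  region_stratified = rep(c(FALSE, TRUE), each = 5),
  setting = c("1", "1", "1", "1", "1S", "2", "2", "2", "2", "2S"),
  stringsAsFactors = FALSE)

#' Scenario specification for the uncertainty-propagation study
#'
#' The study grid crosses the cohort (full, or a 10\% subsample), the
#' size of the general population behind the life table (original, or
#' reduced by a factor of 10, 200 or 2000, i.e. to 10\%, 0.5\% and
#' 0.05\%), and whether the life table is additionally stratified by
#' region.  Labels A-E use sex/age/year stratification (settings 1 and
#' 1S), F-J add region (settings 2 and 2S):
#' A/F factor 1, B/G factor 10, C/H factor 200, D/I factor 2000, and
#' E/J the 10\% cohort with factor 10.
#'
#' @param label One of \code{"A"} ... \code{"J"}; fills the remaining
#'   scenario fields from the grid.
#' @param M Number of replicate rate tables (default 1000).
#' @param seed Master seed driving the cohort subsample and all
#'   coefficient draws.
#' @param cohort_fraction,popmort_factor,region_stratified Optional
#'   explicit values; must agree with the grid entry for \code{label}.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(label, M = 1000L, seed = 1L,
                          cohort_fraction = NULL, popmort_factor = NULL,
                          region_stratified = NULL) {
  label <- match.arg(label, scenario_grid$label)
  g <- scenario_grid[scenario_grid$label == label, ]
  chk <- function(x, ref, what) {
    if (!is.null(x) && !isTRUE(all.equal(x, ref)))
      stop("scenario ", label, " requires ", what, " = ", ref)
  }
  chk(cohort_fraction, g$cohort_fraction, "cohort_fraction")
  chk(popmort_factor, g$popmort_factor, "popmort_factor")
  chk(region_stratified, g$region_stratified, "region_stratified")
  structure(list(label = label, cohort_fraction = g$cohort_fraction,
                 popmort_factor = g$popmort_factor,
                 region_stratified = g$region_stratified,
                 setting = g$setting, M = as.integer(M),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario %s (setting %s): cohort x%.2g, popmort 1/%g, %s; M = %d, seed = %d\n",
    x$label, x$setting, x$cohort_fraction, x$popmort_factor,
    if (x$region_stratified) "region-stratified" else "sex/age/year",
    x$M, x$seed))
  invisible(x)
}

default_profiles <- function(cohort, table, report_region = NULL) {
  yr <- floor(stats::median(cohort$year_dx)) + 0.5
  pr <- expand.grid(age_dx = c(55, 65, 75, 85),
                    sex = c("male", "female"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pr$year_dx <- yr
  if (table$has_region) {
    if (is.null(report_region)) {
      py <- tapply(table$data$person_years, table$data$region, sum)
      report_region <- names(py)[which.max(py)]
    }
    pr$region <- report_region
  }
  pr
}

#' Run one uncertainty-propagation scenario
#'
#' Executes the full pipeline for one [scenario_spec()]:
#' \enumerate{
#'   \item reduce the raw life table by the scenario's population factor
#'     (collapsing regions first when the scenario is not
#'     region-stratified) and, for the small-cohort scenarios, subsample
#'     the cohort;
#'   \item fit the Poisson rate model and take its predictions as the
#'     underlying (fixed) expected rates;
#'   \item fit the relative-survival model conventionally against the
#'     underlying rates and predict 5-year relative survival and loss in
#'     life expectancy, conditionally at the reporting profiles and
#'     marginally over the cohort, with delta-method standard errors;
#'   \item draw \code{M} replicate rate tables from the Poisson model's
#'     coefficient distribution, refit the relative-survival model
#'     against each (warm-started at the conventional optimum) and
#'     recompute every prediction and its standard error;
#'   \item pool the replicate estimates per measure with [pool_rubin()]
#'     and report the relative \% precision against the conventional
#'     standard errors.
#' }
#' Replicates whose refit fails are dropped with a count; the scenario
#' aborts if more than 1\% fail.
#'
#' @param cohort Cancer cohort data frame (see [fit_fpm()]).
#' @param table_raw The raw ("observed") life table, region-stratified
#'   or not; a region-stratified table is collapsed automatically for
#'   scenarios without region stratification.
#' @param spec A [scenario_spec()].
#' @param config An [fpm_config()] for the relative-survival model.
#' @param age_df,year_df Spline df for the Poisson rate model.
#' @param profiles Data frame of reporting profiles; default ages
#'   55/65/75/85 by sex (LLE profiles take \code{report_region}).
#' @param report_region Region for conditional LLE reporting when
#'   stratified; default is the region with the most person-years.
#' @param horizon Integration horizon passed to the LLE engine
#'   (\code{NULL} = per-profile default).
#' @param quad_nodes Gauss-Legendre nodes per band for LLE integration
#'   (default 5 in the replicate loop; the integrand is smooth within
#'   bands, so 5 nodes are already far below the reporting precision).
#' @param zero_rate_cov Force the Poisson coefficient covariance to zero
#'   before drawing replicates: every replicate then equals the
#'   underlying table and the pipeline degenerates to the conventional
#'   analysis (RP = 0) — a pipeline self-check, not an analysis option.
#' @param verbose Print stage progress.
#' @return An object of class \code{scenario_report}: a results data
#'   frame (one row per measure/profile with conventional and pooled
#'   estimate, SE, CI, and RP), the spec, effective M, failure count and
#'   the conventional fit.
#' @export
run_scenario <- function(cohort, table_raw, spec, config = fpm_config(),
                         age_df = 5L, year_df = 3L, profiles = NULL,
                         report_region = NULL, horizon = NULL,
                         quad_nodes = 5L, zero_rate_cov = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(table_raw, "lifetable"))
  say <- function(...) if (verbose) message(...)

  if (!spec$region_stratified && table_raw$has_region)
    table_raw <- collapse_regions(table_raw)
  if (spec$region_stratified && !table_raw$has_region)
    stop("scenario ", spec$label, " needs a region-stratified life table")
  table_red <- if (spec$popmort_factor > 1)
    reduce_size(table_raw, spec$popmort_factor) else table_raw

  if (spec$cohort_fraction < 1) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(child_seed(spec$seed, 99))
    keep <- sample.int(nrow(cohort), round(spec$cohort_fraction * nrow(cohort)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    cohort <- cohort[sort(keep), , drop = FALSE]
  }

  say("fitting Poisson rate model (", nrow(table_red$data), " cells)")
  rm_fit <- fit_poisson_rates(table_red, age_df, year_df)
  if (zero_rate_cov)
    for (r in seq_along(rm_fit$fits))
      rm_fit$fits[[r]]$cov[] <- 0
  underlying <- predict_underlying(rm_fit)

  say("fitting conventional relative-survival model (n = ", nrow(cohort), ")")
  fit <- fit_fpm(cohort, underlying, config)
  if (!fit$converged) stop("conventional model did not converge")

  if (is.null(profiles))
    profiles <- default_profiles(cohort, underlying, report_region)
  np <- nrow(profiles)

  # fixed design pieces reused across replicates
  female_p <- as.numeric(as.character(profiles$sex) == "female")
  X5p <- fpm_design(config, fpm_specs(fit), rep(log(5), np),
                    as.numeric(profiles$age_dx), female_p)$X
  female_c <- as.numeric(as.character(cohort$sex) == "female")
  X5m <- fpm_design(config, fpm_specs(fit), rep(log(5), nrow(cohort)),
                    as.numeric(cohort$age_dx), female_c)$X
  ctx_cond <- lle_context(fit, underlying, profiles, horizon, quad_nodes)
  ctx_marg <- lle_context(fit, underlying, cohort, horizon, quad_nodes)

  predict_all <- function(coef, cov, rate_array) {
    eta <- drop(X5p %*% coef)
    se_eta <- sqrt(pmax(rowSums((X5p %*% cov) * X5p), 0))
    Lam <- exp(eta)
    rs <- exp(-Lam)
    Lm <- exp(drop(X5m %*% coef))
    rsm <- exp(-Lm)
    gm <- -drop(crossprod(X5m, Lm * rsm)) / nrow(X5m)
    ec <- lle_eval(ctx_cond, rate_array, coef)
    se_lle <- sqrt(pmax(rowSums((ec$G %*% cov) * ec$G), 0))
    em <- lle_eval(ctx_marg, rate_array, coef)
    gml <- colMeans(em$G)
    list(est = c(rs, mean(rsm), ec$lle, mean(em$lle)),
         se = c(Lam * rs * se_eta,
                sqrt(max(drop(gm %*% cov %*% gm), 0)),
                se_lle,
                sqrt(max(drop(gml %*% cov %*% gml), 0))))
  }

  conv <- predict_all(fit$coef, fit$cov, underlying$rate_array)

  say("drawing ", spec$M, " replicate rate tables")
  reps <- draw_rate_replicates(rm_fit, spec$M, child_seed(spec$seed, 7),
                               keep_tables = FALSE)

  n_meas <- 2L * (np + 1L)
  EST <- matrix(NA_real_, spec$M, n_meas)
  SE <- matrix(NA_real_, spec$M, n_meas)
  failures <- 0L
  for (m in seq_len(spec$M)) {
    res <- tryCatch({
      tab_m <- replicate_table(reps, m)
      if (identical(tab_m$rate_array, underlying$rate_array)) {
        # degenerate draw: identical inputs give the conventional fit
        fit_m <- fit
      } else {
        fit_m <- fit_fpm(cohort, tab_m, config, init = fit$coef,
                         specs = fit)
        if (!fit_m$converged)  # cold restart via the all-cause pre-fit
          fit_m <- fit_fpm(cohort, tab_m, config, specs = fit)
      }
      if (!fit_m$converged) stop("replicate refit did not converge")
      predict_all(fit_m$coef, fit_m$cov, tab_m$rate_array)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      say("replicate ", m, " failed: ", conditionMessage(res))
    } else {
      EST[m, ] <- res$est
      SE[m, ] <- res$se
    }
    if (verbose && m %% 50 == 0) say("  replicate ", m, "/", spec$M)
  }
  if (failures > 0.01 * spec$M)
    stop("scenario invalid: ", failures, " of ", spec$M,
         " replicate refits failed (> 1%)")
  ok <- !is.na(EST[, 1])

  pooled <- lapply(seq_len(n_meas), function(j)
    pool_rubin(EST[ok, j], SE[ok, j], conv$se[j]))

  meas <- data.frame(
    measure = rep(c("rs5", "lle"), each = np + 1L),
    age = rep(c(profiles$age_dx, NA), 2L),
    sex = rep(c(as.character(profiles$sex), "marginal"), 2L),
    stringsAsFactors = FALSE)
  if (!is.null(profiles$region))
    meas$region <- rep(c(as.character(profiles$region), NA), 2L)
  meas$conv_est <- conv$est
  meas$conv_se <- conv$se
  meas$pool_est <- vapply(pooled, `[[`, 0, "mean")
  meas$pool_se <- vapply(pooled, `[[`, 0, "se_pooled")
  meas$v_within <- vapply(pooled, `[[`, 0, "v_within")
  meas$v_between <- vapply(pooled, `[[`, 0, "v_between")
  meas$rp <- vapply(pooled, `[[`, 0, "rp")
  meas$conv_lci <- meas$conv_est - z975 * meas$conv_se
  meas$conv_uci <- meas$conv_est + z975 * meas$conv_se
  meas$pool_lci <- meas$pool_est - z975 * meas$pool_se
  meas$pool_uci <- meas$pool_est + z975 * meas$pool_se
  rs_rows <- meas$measure == "rs5"
  meas$conv_lci[rs_rows] <- pmax(meas$conv_lci[rs_rows], 0)
  meas$pool_lci[rs_rows] <- pmax(meas$pool_lci[rs_rows], 0)
  meas$conv_uci[rs_rows] <- pmin(meas$conv_uci[rs_rows], 1)
  meas$pool_uci[rs_rows] <- pmin(meas$pool_uci[rs_rows], 1)

  structure(list(results = meas, spec = spec, pooled = pooled,
                 M_effective = sum(ok), failures = failures,
                 conventional_fit = fit, profiles = profiles),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario", x$spec$label, "report (M =", x$M_effective,
      if (x$failures) paste0("; ", x$failures, " failed"), ")\n")
  df <- x$results
  df[vapply(df, is.numeric, TRUE)] <-
    lapply(df[vapply(df, is.numeric, TRUE)], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Combine scenario reports into one comparison table
#'
#' Stacks the per-measure results of one or more [run_scenario()] reports
#' into a tidy data frame (one conventional row with RP fixed at 0 and
#' one bootstrap-based row per scenario and measure), suitable for
#' printing or serialisation.
#'
#' @param reports A single \code{scenario_report} or list of them.
#' @return Data frame with columns \code{scenario}, \code{method},
#'   \code{measure}, \code{age}, \code{sex}, (\code{region},)
#'   \code{estimate}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{rp}.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "scenario_report")) reports <- list(reports)
  out <- lapply(reports, function(r) {
    d <- r$results
    base <- d[c("measure", "age", "sex",
                intersect("region", names(d)))]
    conv <- cbind(scenario = r$spec$label, method = "conventional", base,
                  estimate = d$conv_est, se = d$conv_se,
                  ci_low = d$conv_lci, ci_high = d$conv_uci, rp = 0)
    boot <- cbind(scenario = r$spec$label, method = "bootstrap", base,
                  estimate = d$pool_est, se = d$pool_se,
                  ci_low = d$pool_lci, ci_high = d$pool_uci, rp = d$rp)
    rbind(conv, boot)
  })
  do.call(rbind, out)
}

#' Write / read a scenario comparison table
#'
#' Delimited (comma) serialisation of [report_table()] output at a stated
#' precision; \code{read_report_table()} restores the exact written
#' values, so a write/read round trip is lossless at that precision.
#'
#' @param table Data frame from [report_table()].
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return \code{path} invisibly; for the reader, the data frame.
#' @export
write_report_table <- function(table, path, digits = 6) {
  num <- vapply(table, is.numeric, TRUE)
  table[num] <- lapply(table[num], signif, digits)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Confidence-interval comparison plot
#'
#' Conventional versus bootstrap-based confidence intervals per measure
#' and profile, faceted by measure, in the style of the scenario
#' comparison figures.  Requires ggplot2.
#'
#' @param table Data frame from [report_table()].
#' @return A ggplot object.
#' @export
plot_report_cis <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_report_cis requires ggplot2")
  table$profile <- ifelse(table$sex == "marginal", "marginal",
                          paste(table$sex, table$age))
  ggplot2::ggplot(table, ggplot2::aes(
      x = .data$scenario, y = .data$estimate,
      ymin = .data$ci_low, ymax = .data$ci_high,
      colour = .data$method)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.5),
                             size = 0.3) +
    ggplot2::facet_grid(measure ~ profile, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = "estimate with 95% CI",
                  colour = NULL) +
    ggplot2::theme_bw()
}
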