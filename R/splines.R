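#' Restricted cubic spline specification
#'
#' A restricted cubic spline (RCS) with knots \code{k_1 < ... < k_K} spans
#' functions that are cubic between adjacent knots, have continuous second
#' derivatives everywhere, and are linear beyond the boundary knots.  The
#' basis (excluding the intercept) has \code{K - 1} columns, so the spline
#' contributes \code{df = K - 1} degrees of freedom.  The same basis is used
#' for the baseline log cumulative excess hazard in log time, for
#' time-varying effects, and for age and calendar-year smoothing in the
#' Poisson rate model.
#'
#' @param knots Strictly increasing numeric vector of at least two knots.
#' @return An object of class \code{rcs_spec} with elements \code{knots} and
#'   \code{df}.
#' @seealso [rcs_basis()], [rcs_deriv()], [default_knots()]
#' @export
rcs_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L)
    stop("an RCS specification needs at least 2 knots")
  if (anyNA(knots) || any(!is.finite(knots)))
    stop("knots must be finite")
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing")
  structure(list(knots = knots, df = length(knots) - 1L),
            class = "rcs_spec")
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat("Restricted cubic spline: df =", x$df, "\n")
  cat("  knots:", paste(signif(x$knots, 6), collapse = ", "), "\n")
  invisible(x)
}

pos3 <- function(u) {
  u[u < 0] <- 0
  u^3
}

pos2 <- function(u) {
  u[u < 0] <- 0
  u^2
}

#' Restricted cubic spline basis
#'
#' Evaluates the truncated-power RCS basis.  Column 1 is \code{x} itself;
#' column \code{j} (for interior knot \code{k_j}, \code{j = 2, ..., K - 1})
#' is
#' \deqn{(x - k_j)_+^3 - \lambda_j (x - k_1)_+^3 - (1 - \lambda_j)(x - k_K)_+^3,}
#' with \eqn{\lambda_j = (k_K - k_j) / (k_K - k_1)}.  The restriction makes
#' every column (hence any linear combination) linear in \code{x} outside
#' the boundary knots, which is the mechanism by which fitted relative
#' survival is extrapolated beyond follow-up on the log cumulative hazard
#' scale.
#'
#' The raw truncated-power form is used without orthogonalisation so that
#' coefficients map directly onto the knots; for knot ranges of a few units
#' (log time in years, age in decades) conditioning is unproblematic, but
#' very wide ranges may warrant rescaling \code{x} before knot placement.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec An [rcs_spec()].
#' @return Numeric matrix, \code{length(x)} rows and \code{spec$df} columns.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  k <- spec$knots
  K <- length(k)
  x <- as.numeric(x)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- x
  if (K > 2L) {
    lam <- (k[K] - k[-c(1L, K)]) / (k[K] - k[1L])
    for (j in seq_len(K - 2L)) {
      out[, j + 1L] <- pos3(x - k[j + 1L]) -
        lam[j] * pos3(x - k[1L]) - (1 - lam[j]) * pos3(x - k[K])
    }
  }
  out
}

#' Derivative of the restricted cubic spline basis
#'
#' Exact analytic derivative of each [rcs_basis()] column with respect to
#' \code{x}.  Needed to form the excess hazard
#' \eqn{\lambda(t) = \Lambda(t)\, \eta'(\ln t) / t} from the fitted log
#' cumulative hazard \eqn{\eta(\ln t)}.
#'
#' @inheritParams rcs_basis
#' @return Numeric matrix matching [rcs_basis()] in shape.
#' @export
rcs_deriv <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  k <- spec$knots
  K <- length(k)
  x <- as.numeric(x)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- 1
  if (K > 2L) {
    lam <- (k[K] - k[-c(1L, K)]) / (k[K] - k[1L])
    for (j in seq_len(K - 2L)) {
      out[, j + 1L] <- 3 * (pos2(x - k[j + 1L]) -
        lam[j] * pos2(x - k[1L]) - (1 - lam[j]) * pos2(x - k[K]))
    }
  }
  out
}

#' Weighted quantile by linear interpolation of the empirical CDF
#'
#' Sorts \code{x}, assigns each sorted value the plotting position
#' \eqn{(\sum_{i \le j} w_i - w_j / 2) / \sum w}, and linearly interpolates.
#' Probabilities outside the plotting-position range are clamped to the
#' extreme order statistics.  With equal weights this reduces to the
#' mid-point (type 5) sample quantile; the fixed convention keeps knot
#' placement deterministic across platforms.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in \[0, 1\].
#' @param weights Optional positive weights, recycled checked to length of
#'   \code{x}; \code{NULL} means equal weights.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, probs, weights = NULL) {
  stopifnot(all(probs >= 0), all(probs <= 1))
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x))
    stop("weights must match x in length")
  if (any(weights <= 0)) stop("weights must be positive")
  o <- order(x)
  x <- x[o]
  w <- weights[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Default knot placement for a restricted cubic spline
#'
#' Boundary knots at the minimum and maximum of \code{values}; for
#' \code{df >= 2}, the \code{df - 1} interior knots sit at the quantiles
#' \code{j / df}, \code{j = 1, ..., df - 1}, computed by
#' [weighted_quantile()].  Weights (for example person-years when placing
#' age or calendar-year knots for a rate model) shift the interior knots
#' toward well-populated regions; equal weights reproduce the unweighted
#' placement.
#'
#' @param values Numeric vector the spline will be applied to (event log
#'   times, ages, years, ...).
#' @param df Spline degrees of freedom (number of basis columns), at
#'   least 1; the spline has \code{df + 1} knots.
#' @param weights Optional positive weights for the quantile computation.
#' @return An [rcs_spec()].
#' @export
default_knots <- function(values, df, weights = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  df <- as.integer(df)
  if (df < 1L) stop("df must be at least 1")
  rng <- range(values)
  if (rng[1] == rng[2]) stop("values are all identical; cannot place knots")
  interior <- if (df >= 2L)
    weighted_quantile(values, seq_len(df - 1L) / df, weights)
  else numeric(0)
  knots <- sort(unique(c(rng[1], interior, rng[2])))
  if (length(knots) != df + 1L)
    stop("degenerate knot placement: ties in quantiles reduce df; ",
         "supply fewer df or explicit knots")
  rcs_spec(knots)
}
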