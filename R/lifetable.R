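#' Stratified population life table
#'
#' Container for a "popmort"-style table of general-population death counts
#' and person-years, stratified by sex, single year of age and single
#' calendar year, optionally further by region.  A cell for age \code{a}
#' and year \code{y} covers attained ages \code{[a, a + 1)} and dates
#' \code{[y, y + 1)} (half-open single-year bands), so the expected hazard
#' is piecewise constant over the grid and expected survival integrates
#' exactly band by band.
#'
#' The grid must be complete: exactly one cell for every combination of
#' sex, age and year (and region when present) within the declared ranges.
#' Fractional death counts are allowed, because reducing a table in size
#' divides both deaths and person-years by a scale factor.
#'
#' @param data Data frame with columns \code{sex} (\code{"male"} /
#'   \code{"female"}), \code{age} (integer years), \code{year} (integer
#'   calendar year), optionally \code{region}, and \code{deaths}
#'   (non-negative, possibly fractional) and \code{person_years}
#'   (strictly positive).
#' @return An object of class \code{lifetable} with elements \code{data}
#'   (the validated cells, ordered), \code{age_range}, \code{year_range},
#'   \code{sexes}, \code{regions} (\code{NULL} when unstratified),
#'   \code{has_region}, and an internal rate array for constant-time
#'   lookup.
#' @seealso [read_lifetable()], [reduce_size()], [lookup_rate()]
#' @export
lifetable <- function(data) {
  req <- c("sex", "age", "year", "deaths", "person_years")
  if (!all(req %in% names(data)))
    stop("life table needs columns: ", paste(req, collapse = ", "))
  has_region <- "region" %in% names(data)
  data$sex <- as.character(data$sex)
  bad_sex <- setdiff(unique(data$sex), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex level(s): ", paste(bad_sex, collapse = ", "))
  if (any(data$age != floor(data$age)) || any(data$year != floor(data$year)))
    stop("age and year must be integer-valued")
  data$deaths <- as.numeric(data$deaths)
  data$person_years <- as.numeric(data$person_years)
  data$age <- as.numeric(data$age)
  data$year <- as.numeric(data$year)
  if (anyNA(data$deaths) || any(data$deaths < 0))
    stop("deaths must be non-negative")
  if (anyNA(data$person_years) || any(data$person_years <= 0))
    stop("person_years must be strictly positive")

  sexes <- sort(unique(data$sex), decreasing = TRUE)   # male, female
  ages <- seq(min(data$age), max(data$age))
  years <- seq(min(data$year), max(data$year))
  regions <- if (has_region) sort(unique(as.character(data$region))) else NULL
  if (has_region) data$region <- as.character(data$region)

  n_expect <- length(sexes) * length(ages) * length(years) *
    max(1L, length(regions))
  key <- paste(data$sex, data$age, data$year,
               if (has_region) data$region else "")
  if (anyDuplicated(key))
    stop("duplicated stratum (sex, age, year", if (has_region) ", region",
         ") in life table")
  if (nrow(data) != n_expect)
    stop("incomplete grid: expected ", n_expect, " cells within ranges, got ",
         nrow(data))

  # dense rate array [sex, age, year, region] for O(1) vectorised lookup
  si <- match(data$sex, sexes)
  ai <- data$age - ages[1] + 1L
  yi <- data$year - years[1] + 1L
  ri <- if (has_region) match(data$region, regions) else rep(1L, nrow(data))
  dims <- c(length(sexes), length(ages), length(years), max(1L, length(regions)))
  arr <- array(NA_real_, dims)
  lin <- si + dims[1] * (ai - 1L + dims[2] * (yi - 1L + dims[3] * (ri - 1L)))
  arr[lin] <- data$deaths / data$person_years
  py_arr <- array(NA_real_, dims)
  py_arr[lin] <- data$person_years

  o <- order(ri, si, ai, yi)
  structure(list(
    data = data[o, , drop = FALSE],
    age_range = range(ages), year_range = range(years),
    sexes = sexes, regions = regions, has_region = has_region,
    rate_array = arr, py_array = py_arr, cell_index = lin[o]
  ), class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Population life table:", nrow(x$data), "cells\n")
  cat("  ages", x$age_range[1], "-", x$age_range[2],
      "; years", x$year_range[1], "-", x$year_range[2], "\n")
  if (x$has_region)
    cat("  regions:", length(x$regions), "\n")
  cat("  crude rate range:",
      format(range(x$data$deaths / x$data$person_years), digits = 4), "\n")
  invisible(x)
}

#' Read a population life table from a delimited file
#'
#' Accepts tab- or comma-delimited UTF-8 text with a header row and columns
#' \code{sex,age,year[,region],deaths,person_years}.  The delimiter is
#' sniffed from the header line.  Validation (complete grid, no duplicate
#' strata, non-negative counts) happens in [lifetable()].
#'
#' @param path File path.
#' @param has_region Whether a \code{region} column is required.
#' @return A [lifetable()].
#' @export
read_lifetable <- function(path, has_region = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sex", "age", "year", if (has_region) "region",
            "deaths", "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("life-table file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!has_region) df$region <- NULL
  lifetable(df[need])
}

#' Write a life table to a delimited file
#'
#' Inverse of [read_lifetable()]: writes the cells with full precision so
#' that a read/write round trip is lossless.
#'
#' @param table A [lifetable()].
#' @param path Output file path.
#' @param sep Field separator, tab by default.
#' @return \code{path}, invisibly.
#' @export
write_lifetable <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "lifetable"))
  df <- table$data
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Reduce a life table in size
#'
#' Divides both deaths and person-years by \code{factor} in every cell,
#' emulating a life table built from a population \code{1/factor} the
#' size of the original.  Rates are unchanged exactly; only the
#' information content (and hence the sampling variance of any model
#' fitted to the table) is reduced.
#'
#' @param table A [lifetable()].
#' @param factor Scale factor, at least 1.
#' @return A [lifetable()] with scaled counts.
#' @export
reduce_size <- function(table, factor) {
  stopifnot(inherits(table, "lifetable"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("factor must be a single number >= 1")
  df <- table$data
  df$deaths <- df$deaths / factor
  df$person_years <- df$person_years / factor
  lifetable(df)
}

#' Look up expected mortality rates
#'
#' Returns the piecewise-constant rate at the cell containing
#' (\code{floor(attained_age)}, \code{floor(attained_year)}).  Indices
#' outside the table's declared ranges are clamped to the nearest boundary
#' cell, so rates persist at their boundary values for attained ages above
#' the oldest tabulated age and calendar years beyond the last tabulated
#' year.  This clamping is what makes extrapolated expected survival (and
#' hence loss in life expectancy over a long horizon) well defined.
#'
#' All of \code{sex}, \code{attained_age}, \code{attained_year} and
#' \code{region} are vectorised and recycled to a common length.
#'
#' @param table A [lifetable()].
#' @param sex \code{"male"} / \code{"female"}.
#' @param attained_age Attained age in (possibly fractional) years.
#' @param attained_year Attained calendar time in (possibly fractional)
#'   years.
#' @param region Region label; required when the table is
#'   region-stratified, must be absent (or NULL) otherwise.
#' @return Numeric vector of rates per person-year.
#' @export
lookup_rate <- function(table, sex, attained_age, attained_year,
                        region = NULL) {
  stopifnot(inherits(table, "lifetable"))
  idx <- lifetable_cell_index(table, sex, attained_age, attained_year, region)
  table$rate_array[idx]
}

#' Collapse a region-stratified life table over regions
#'
#' Sums deaths and person-years across regions within each (sex, age,
#' year) stratum, producing the national-level table implied by the
#' regional one.
#'
#' @param table A region-stratified [lifetable()].
#' @return A [lifetable()] without region stratification.
#' @export
collapse_regions <- function(table) {
  stopifnot(inherits(table, "lifetable"))
  if (!table$has_region) return(table)
  d <- table$data
  agg <- stats::aggregate(d[c("deaths", "person_years")],
                          by = d[c("sex", "age", "year")], FUN = sum)
  lifetable(agg)
}

# Linear index into the rate array, with boundary clamping.  Shared by
# lookup_rate and the vectorised survival-integration engine so that a
# set of replicate tables on the same grid can be indexed once.
lifetable_cell_index <- function(table, sex, attained_age, attained_year,
                                 region = NULL) {
  n <- max(length(sex), length(attained_age), length(attained_year),
           length(region))
  sex <- rep_len(as.character(sex), n)
  si <- match(sex, table$sexes)
  if (anyNA(si))
    stop("sex level(s) not present in table: ",
         paste(unique(sex[is.na(si)]), collapse = ", "))
  if (table$has_region) {
    if (is.null(region)) stop("table is region-stratified; region required")
    region <- rep_len(as.character(region), n)
    ri <- match(region, table$regions)
    if (anyNA(ri))
      stop("region(s) not present in table: ",
           paste(unique(region[is.na(ri)]), collapse = ", "))
  } else {
    if (!is.null(region)) stop("table has no region stratification")
    ri <- rep_len(1L, n)
  }
  ai <- pmin(pmax(floor(rep_len(attained_age, n)), table$age_range[1]),
             table$age_range[2]) - table$age_range[1] + 1
  yi <- pmin(pmax(floor(rep_len(attained_year, n)), table$year_range[1]),
             table$year_range[2]) - table$year_range[1] + 1
  d <- dim(table$rate_array)
  si + d[1] * (ai - 1 + d[2] * (yi - 1 + d[3] * (ri - 1)))
}
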