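#' Age-indexed knot table
#'
#' Container for a tabulated age trend (body weight, beta cell density,
#' pancreas volume, ...) to be interpolated by a cubic spline. Ages are in
#' decimal years; values carry curve-specific units (kg for weight, abstract
#' BCM-units per cm^3 for beta cell density, cm^3 for pancreas volume).
#'
#' @param ages Numeric vector of ages in years, strictly increasing.
#' @param values Numeric vector of the same length; all finite.
#' @param positive Require all values to be strictly positive (appropriate
#'   for weight, mass and volume tables). Default `FALSE`.
#' @return An object of class `age_knots`.
#' @export
age_knots <- function(ages, values, positive = FALSE) {
  if (!is.numeric(ages) || !is.numeric(values))
    stop("ages and values must be numeric", call. = FALSE)
  if (length(ages) != length(values))
    stop("ages and values must have the same length", call. = FALSE)
  if (anyNA(ages) || anyNA(values) || any(!is.finite(ages)) || any(!is.finite(values)))
    stop("ages and values must be finite", call. = FALSE)
  if (anyDuplicated(ages))
    stop("duplicate ages in knot table", call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing", call. = FALSE)
  if (positive && any(values <= 0))
    stop("values must be strictly positive for this curve type", call. = FALSE)
  structure(list(ages = as.numeric(ages), values = as.numeric(values)),
            class = "age_knots")
}

#' @export
print.age_knots <- function(x, ...) {
  cat("<age_knots> ", length(x$ages), " knots over [",
      min(x$ages), ", ", max(x$ages), "] years\n", sep = "")
  invisible(x)
}

#' Read a knot table from CSV
#'
#' Expects a header row with columns `age_years,value` ('.' decimal,
#' UTF-8, comma separated).
#'
#' @param path Path to the CSV file.
#' @param positive Passed on to [age_knots()].
#' @return An `age_knots` object.
#' @export
read_knots_csv <- function(path, positive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("age_years", "value")
  if (!all(req %in% names(df)))
    stop("knot CSV must have columns 'age_years' and 'value': ", path,
         call. = FALSE)
  o <- order(df$age_years)
  age_knots(df$age_years[o], df$value[o], positive = positive)
}

#' Fit a natural cubic spline through a knot table
#'
#' Natural boundary conditions (zero second derivative at both ends) are
#' used throughout: the conventional choice for sparse biological trend
#' data, avoiding spurious curvature at the ends of the age range.
#'
#' @param knots An [age_knots()] object with at least 3 knots.
#' @return An object of class `age_curve` interpolating every knot exactly,
#'   with continuous first and second derivatives at interior knots.
#'   Evaluation outside the knot range clamps to the boundary value (see
#'   [evaluate_curve()]).
#' @export
fit_cubic_spline <- function(knots) {
  if (!inherits(knots, "age_knots"))
    knots <- age_knots(knots$ages, knots$values)
  if (length(knots$ages) < 3)
    stop("a cubic spline needs at least 3 knots", call. = FALSE)
  f <- stats::splinefun(knots$ages, knots$values, method = "natural")
  structure(list(knots = knots,
                 fun = f,
                 domain = range(knots$ages)),
            class = "age_curve")
}

#' @export
print.age_curve <- function(x, ...) {
  cat("<age_curve> natural cubic spline, ", length(x$knots$ages),
      " knots, domain [", x$domain[1], ", ", x$domain[2], "] years\n",
      sep = "")
  invisible(x)
}

#' Evaluate an age curve
#'
#' Piecewise-cubic evaluation inside the knot domain; ages outside the
#' domain are clamped to the nearest boundary, so the curve is constant
#' beyond its first and last knot (cubic extrapolation of sparse growth
#' tables blows up and the source tables end near age 20-25).
#'
#' @param curve An `age_curve`.
#' @param age Numeric vector of ages in years; must be finite.
#' @return Numeric vector of curve values.
#' @export
evaluate_curve <- function(curve, age) {
  stopifnot(inherits(curve, "age_curve"))
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age)))
    stop("age must be finite", call. = FALSE)
  a <- pmin(pmax(age, curve$domain[1]), curve$domain[2])
  curve$fun(a)
}

#' @export
predict.age_curve <- function(object, age, ...) evaluate_curve(object, age)

#' Average male and female growth-chart tables
#'
#' Resamples both weight-for-age tables onto the union of their age grids
#' (restricted to the overlapping age range) via their natural splines and
#' takes the pointwise arithmetic mean, giving the sex-averaged body weight
#' table W(a).
#'
#' @param male,female [age_knots()] weight tables (kg).
#' @return An `age_knots` table of mean weights on the union grid.
#' @export
average_growth_chart <- function(male, female) {
  if (!inherits(male, "age_knots") || !inherits(female, "age_knots"))
    stop("both male and female knot tables are required", call. = FALSE)
  lo <- max(min(male$ages), min(female$ages))
  hi <- min(max(male$ages), max(female$ages))
  if (lo >= hi)
    stop("male and female age grids do not overlap", call. = FALSE)
  grid <- sort(unique(c(male$ages, female$ages)))
  grid <- grid[grid >= lo & grid <= hi]
  vm <- evaluate_curve(fit_cubic_spline(male), grid)
  vf <- evaluate_curve(fit_cubic_spline(female), grid)
  age_knots(grid, (vm + vf) / 2, positive = TRUE)
}

#' Total beta cell mass curve as a product of two splines
#'
#' The age trend in total beta cell mass BCM(a) is the product of the beta
#' cell density trend and the pancreas volume trend. The product of the two
#' cubic splines is sampled on a dense age grid over the shared domain
#' (a uniform grid plus the union of the input knot ages, so the product is
#' exact at shared knots) and re-fit with a natural spline, so downstream
#' code handles a single curve type.
#'
#' @param density,volume `age_curve` objects with overlapping domains.
#' @param n_grid Number of uniform grid points (default 200; the re-splined
#'   product stays within 0.5% of the pointwise product at this density).
#' @return An `age_curve` for BCM(a) on the overlapping domain.
#' @export
bcm_total_curve <- function(density, volume, n_grid = 200) {
  stopifnot(inherits(density, "age_curve"), inherits(volume, "age_curve"))
  lo <- max(density$domain[1], volume$domain[1])
  hi <- min(density$domain[2], volume$domain[2])
  if (lo >= hi)
    stop("density and volume curve domains do not overlap", call. = FALSE)
  kn <- c(density$knots$ages, volume$knots$ages)
  grid <- sort(unique(c(seq(lo, hi, length.out = n_grid),
                        kn[kn >= lo & kn <= hi])))
  vals <- evaluate_curve(density, grid) * evaluate_curve(volume, grid)
  fit_cubic_spline(age_knots(grid, vals))
}
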