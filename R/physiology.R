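#' Steady-state insulin balance model
#'
#' Couples the age-dependent body weight curve W(a) and total beta cell
#' mass curve BCM(a) through a lumped insulin-demand parameter `alpha`
#' (BCM-units per kg of body weight). The model states that the minimum
#' beta cell mass required to maintain euglycemia is proportional to body
#' weight, `BCM_min(a) = alpha * W(a)`, where
#' `alpha = k_clr * C_fast / (rho * q_max)` lumps the insulin clearance
#' rate constant, the fasting insulin set-point, body density, and the
#' maximum insulin release rate per unit beta cell mass. Only `alpha` is
#' identifiable from islet histopathology, so the mechanistic constants
#' default to 1 and are carried for dimensional bookkeeping.
#'
#' @param weight_curve `age_curve` for body weight W(a) in kg.
#' @param bcm_curve `age_curve` for total beta cell mass BCM(a)
#'   (abstract BCM-units, used consistently with `alpha`).
#' @param alpha Demand parameter, BCM-units per kg; > 0.
#' @param qmax Maximum insulin release per BCM-unit per time (default 1).
#' @param kclr Insulin clearance rate constant, per time (default 1).
#' @param rho Body density, kg per L (default 1).
#' @param gamma Plasma C-peptide per unit insulin concentration
#'   (proportionality constant, assumed disease-state independent;
#'   default 1).
#' @return An object of class `physiology_model`.
#' @export
physiology_model <- function(weight_curve, bcm_curve, alpha,
                             qmax = 1, kclr = 1, rho = 1, gamma = 1) {
  stopifnot(inherits(weight_curve, "age_curve"),
            inherits(bcm_curve, "age_curve"))
  for (nm in c("alpha", "qmax", "kclr", "rho", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive finite number", call. = FALSE)
  }
  if (max(weight_curve$domain[1], bcm_curve$domain[1]) >=
      min(weight_curve$domain[2], bcm_curve$domain[2]))
    stop("weight and BCM curve domains do not overlap", call. = FALSE)
  structure(list(alpha = alpha, qmax = qmax, kclr = kclr, rho = rho,
                 gamma = gamma, weight_curve = weight_curve,
                 bcm_curve = bcm_curve),
            class = "physiology_model")
}

#' @export
print.physiology_model <- function(x, ...) {
  cat("<physiology_model> alpha =", x$alpha, "BCM-units/kg",
      "(qmax", x$qmax, ", kclr", x$kclr, ", rho", x$rho,
      ", gamma", x$gamma, ")\n")
  invisible(x)
}

#' Right-hand side of the insulin balance ODE
#'
#' Rate of change of the whole-body insulin amount N: a source proportional
#' to beta cell mass and a clearance sink proportional to plasma insulin
#' concentration times body volume,
#' `dN/dt = qmax * bcm - kclr * insulin_conc * W(age) / rho`.
#' Every downstream quantity uses the fasting steady state (dN/dt = 0), so
#' this function documents the transient balance; it is not integrated.
#'
#' @param model A `physiology_model`.
#' @param insulin_conc Plasma insulin concentration.
#' @param bcm Beta cell mass, BCM-units.
#' @param age Age in years.
#' @return dN/dt in insulin amount per unit time.
#' @export
insulin_balance_rhs <- function(model, insulin_conc, bcm, age) {
  stopifnot(inherits(model, "physiology_model"))
  W <- evaluate_curve(model$weight_curve, age)
  model$qmax * bcm - model$kclr * insulin_conc * W / model$rho
}

#' Minimum beta cell mass required for euglycemia
#'
#' `BCM_min(a) = alpha * W(a)`: the demand for insulin scales with body
#' weight, so the minimum mass tracks the growth curve.
#'
#' @param model A `physiology_model`.
#' @param age Age(s) in years (clamped to the weight-curve domain).
#' @return Minimum beta cell mass in BCM-units.
#' @export
minimum_bcm <- function(model, age) {
  stopifnot(inherits(model, "physiology_model"))
  model$alpha * evaluate_curve(model$weight_curve, age)
}

#' Normalized excess beta cell mass
#'
#' Decomposes the total mass as BCM(a) = BCM_min(a) + BCM_excess(a) and
#' returns the normalized excess `ebcm = 1 - alpha * W(a) / BCM(a)`: the
#' fraction of beta cell mass that can be lost before hyperglycemia, equal
#' under the model to the tolerable fraction of insulin-deficient islets.
#' Values may be negative (demand exceeding total mass) and are not
#' clamped; observed islet fractions are clamped at ingestion instead.
#'
#' @param model A `physiology_model`.
#' @param age Age(s) in years.
#' @return A data.frame with columns `age`, `bcm_total`, `bcm_min`, `ebcm`.
#' @export
excess_bcm <- function(model, age) {
  stopifnot(inherits(model, "physiology_model"))
  bcm_total <- evaluate_curve(model$bcm_curve, age)
  if (any(bcm_total <= 0))
    stop("total beta cell mass curve is non-positive at a requested age",
         call. = FALSE)
  bcm_min <- minimum_bcm(model, age)
  data.frame(age = age, bcm_total = bcm_total, bcm_min = bcm_min,
             ebcm = 1 - bcm_min / bcm_total)
}

#' Steady-state (fasting) plasma insulin concentration
#'
#' Rearranging the insulin balance at steady state:
#' `C_I = qmax * rho * bcm / (kclr * W(age))`. Proportional to the beta
#' cell mass and inversely proportional to body weight; when
#' `bcm = BCM_min(age)` this reduces to the age-independent fasting
#' set-point `qmax * rho * alpha / kclr`.
#'
#' @param model A `physiology_model`.
#' @param bcm Beta cell mass, BCM-units (>= 0).
#' @param age Age(s) in years.
#' @return Plasma insulin concentration.
#' @export
steady_state_insulin <- function(model, bcm, age) {
  stopifnot(inherits(model, "physiology_model"))
  if (any(bcm < 0)) stop("bcm must be non-negative", call. = FALSE)
  W <- evaluate_curve(model$weight_curve, age)
  if (any(W <= 0)) stop("body weight must be positive", call. = FALSE)
  model$qmax * model$rho * bcm / (model$kclr * W)
}

#' Predicted plasma C-peptide concentration
#'
#' C-peptide is co-secreted 1:1 with insulin, so the observed plasma level
#' is taken proportional to the predicted steady-state insulin
#' concentration with a disease-state-independent constant `gamma`. Below
#' the minimum mass the prediction falls below the fasting set-point:
#' increased per-cell secretion cannot compensate for lost mass.
#'
#' @inheritParams steady_state_insulin
#' @return Predicted plasma C-peptide concentration
#'   (`gamma` times the insulin concentration).
#' @export
predicted_cpeptide <- function(model, bcm, age) {
  model$gamma * steady_state_insulin(model, bcm, age)
}

#' Fixed-threshold comparator predictor
#'
#' The prevailing fixed-loss account holds that a constant fraction of beta
#' cells (commonly quoted as 80-95\%) is destroyed at onset regardless of
#' age. This returns an age-independent EBCM predictor for side-by-side
#' comparison with the physiological model.
#'
#' @param threshold Fraction in (0, 1).
#' @return A function of age returning `threshold` for every age, with
#'   class `ebcm_predictor`.
#' @export
fixed_threshold_ebcm <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  structure(function(age) rep(threshold, length(age)),
            class = c("ebcm_predictor", "function"),
            threshold = threshold)
}

#' Default physiology model from packaged fixture curves
#'
#' Builds W(a) as the sex-averaged weight curve from the packaged
#' (synthetic, stand-in) male/female growth-chart tables and BCM(a) as the
#' product of the packaged beta cell density and pancreas volume splines.
#' The fixtures are scaled so that BCM(20)/W(20) = 829 BCM-units/kg, i.e.
#' ebcm(20) = 1 - 499/829 ~ 0.40 at the default `alpha`, with ~85\%
#' predicted reduction at the youngest ages.
#'
#' @param alpha Demand parameter (default 499 BCM-units/kg, the published
#'   point estimate).
#' @param ... Passed to [physiology_model()] (`gamma`, `qmax`, ...).
#' @return A `physiology_model`.
#' @export
default_model <- function(alpha = 499, ...) {
  path <- function(f) system.file("extdata", f, package = "ebcm",
                                  mustWork = TRUE)
  wm <- read_knots_csv(path("weight_male.csv"), positive = TRUE)
  wf <- read_knots_csv(path("weight_female.csv"), positive = TRUE)
  dens <- fit_cubic_spline(read_knots_csv(path("beta_cell_density.csv"),
                                          positive = TRUE))
  vol <- fit_cubic_spline(read_knots_csv(path("pancreas_volume.csv"),
                                         positive = TRUE))
  w <- fit_cubic_spline(average_growth_chart(wm, wf))
  physiology_model(weight_curve = w,
                   bcm_curve = bcm_total_curve(dens, vol),
                   alpha = alpha, ...)
}
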