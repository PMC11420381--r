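#' Sigmoid transformation parameters
#'
#' Constructor for the parameters of the sigmoid Emax (Hill) transformation
#' used to normalize trough concentrations onto the 0-100 transformed trough
#' concentration (TTC) scale.
#'
#' @param ec50 Concentration at the centre of the sigmoid (ng/mL); the
#'   concentration mapped to TTC = 50. Default 600 ng/mL, slightly above the
#'   common 435 ng/mL therapeutic target.
#' @param gamma Steepness exponent of the curve (dimensionless, > 0).
#'   Default 1.5, which reproduces the one-unit-increase concentration pairs
#'   used to interpret the association estimates (see
#'   [unit_increase_equivalent()]).
#' @param scale Output ceiling; fixed at 100 so TTC lies in \[0, 100).
#' @return An object of class `sigmoid_params`.
#' @seealso [ttc()], [inverse_ttc()], [calibrate_gamma()]
#' @export
#' @examples
#' sigmoid_params()                 # main analysis
#' sigmoid_params(ec50 = 500, gamma = 2)  # sensitivity preset
sigmoid_params <- function(ec50 = 600, gamma = 1.5, scale = 100) {
  stopifnot(is.numeric(ec50), length(ec50) == 1L, is.finite(ec50), ec50 > 0,
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0,
            identical(as.numeric(scale), 100))
  structure(list(ec50 = ec50, gamma = gamma, scale = 100),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("Sigmoid TTC transform: EC50 = %g ng/mL, gamma = %g, scale = %g\n",
              x$ec50, x$gamma, x$scale))
  invisible(x)
}

#' Pharmacokinetic constants for trough extrapolation
#'
#' @param half_life_h Plasma elimination half-life in hours (default 32 h,
#'   the literature value for alectinib).
#' @param dosing_interval_h Hours between scheduled intakes (default 12 h,
#'   twice-daily dosing).
#' @return An object of class `pk_constants`.
#' @export
pk_constants <- function(half_life_h = 32, dosing_interval_h = 12) {
  stopifnot(is.numeric(half_life_h), length(half_life_h) == 1L, half_life_h > 0,
            is.numeric(dosing_interval_h), length(dosing_interval_h) == 1L,
            dosing_interval_h > 0)
  structure(list(half_life_h = half_life_h,
                 dosing_interval_h = dosing_interval_h),
            class = "pk_constants")
}

#' Extrapolate a plasma sample to the trough concentration
#'
#' Samples drawn at routine visits are rarely true troughs. Using the time
#' since the last intake, the measured concentration is decayed log-linearly
#' forward to the next scheduled trough, i.e. the moment immediately before
#' the next intake:
#' \deqn{C_{trough} = C_{obs} \cdot 2^{-\Delta / t_{1/2}},\qquad
#'       \Delta = (\tau - (t_{sld} \bmod \tau)) \bmod \tau,}
#' where \eqn{\tau} is the dosing interval and \eqn{t_{sld}} the hours since
#' the last dose. A sample taken exactly at trough (\eqn{\Delta = 0}) is
#' returned unchanged, and times beyond one interval (late or missed intakes)
#' are reduced modulo the interval.
#'
#' @param conc_obs Measured plasma concentration(s), ng/mL, > 0. Vectorised.
#' @param t_since_dose Hours since last intake, >= 0. Recycled with `conc_obs`.
#' @param constants A [pk_constants()] object.
#' @return Trough concentration(s) in ng/mL, never exceeding `conc_obs`.
#' @export
#' @examples
#' extrapolate_trough(500, t_since_dose = 4)   # 420.448 ng/mL
#' extrapolate_trough(500, t_since_dose = 12)  # at trough: unchanged
extrapolate_trough <- function(conc_obs, t_since_dose, constants = pk_constants()) {
  stopifnot(inherits(constants, "pk_constants"))
  if (!is.numeric(conc_obs) || any(!is.finite(conc_obs)) || any(conc_obs <= 0))
    stop("'conc_obs' must be finite and strictly positive (ng/mL)")
  if (!is.numeric(t_since_dose) || any(!is.finite(t_since_dose)) ||
      any(t_since_dose < 0))
    stop("'t_since_dose' must be finite and non-negative (hours)")
  tau <- constants$dosing_interval_h
  delta <- (tau - (t_since_dose %% tau)) %% tau
  conc_obs * 2^(-delta / constants$half_life_h)
}

#' Transformed trough concentration (TTC)
#'
#' Maps a trough concentration onto the bounded 0-100 TTC scale through the
#' sigmoid Emax curve
#' \deqn{TTC = \frac{C^{\gamma}}{EC_{50}^{\gamma} + C^{\gamma}} \times 100.}
#' The transform normalizes right-skewed concentration data and encodes the
#' saturating concentration-effect relationship: above the EC50 the TTC
#' increases less than proportionally with concentration.
#'
#' @param conc Trough concentration(s), ng/mL, >= 0. Vectorised.
#' @param params A [sigmoid_params()] object.
#' @return TTC value(s) in \[0, 100).
#' @export
#' @examples
#' ttc(600)        # 50: the centre of the curve
#' ttc(c(0, 350, 1200))
ttc <- function(conc, params = sigmoid_params()) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be finite and non-negative (ng/mL)")
  r <- (conc / params$ec50)^params$gamma
  params$scale * r / (1 + r)
}

#' Inverse TTC transformation
#'
#' Returns the trough concentration whose TTC equals `value`. Exact inverse
#' of [ttc()]: `ttc(inverse_ttc(v)) == v` up to floating point.
#'
#' @param value TTC value(s) in \[0, 100); 100 is unreachable.
#' @param params A [sigmoid_params()] object.
#' @return Concentration(s) in ng/mL.
#' @export
inverse_ttc <- function(value, params = sigmoid_params()) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (!is.numeric(value) || any(!is.finite(value)) ||
      any(value < 0) || any(value >= params$scale))
    stop("'value' must lie in [0, 100); 100 is the unreachable asymptote")
  p <- value / params$scale
  params$ec50 * (p / (1 - p))^(1 / params$gamma)
}

#' Calibrate the sigmoid steepness for normality of the TTC
#'
#' The steepness exponent gamma is fixed empirically so that the transformed
#' sample is approximately Gaussian, a working assumption of the linear
#' mixed-effects sub-model. Each candidate on the grid is scored by the
#' Shapiro-Wilk W statistic of the transformed concentrations; the candidate
#' with the largest W wins, ties broken toward the smaller gamma.
#'
#' @param concentrations Numeric vector of trough concentrations (ng/mL),
#'   at least 10 values (the normality score is unstable below that).
#' @param ec50 Fixed EC50 of the transform (ng/mL).
#' @param grid Candidate gamma values (> 0). Default 0.5 to 4 in steps of 0.25.
#' @return The selected gamma (scalar), with the score table in attribute
#'   `"scores"`.
#' @export
calibrate_gamma <- function(concentrations, ec50 = 600,
                            grid = seq(0.5, 4, by = 0.25)) {
  if (!is.numeric(concentrations) || length(concentrations) < 10)
    stop("need at least 10 concentrations to score normality")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative")
  if (stats::sd(concentrations) == 0)
    stop("degenerate sample: all concentrations identical")
  if (!is.numeric(grid) || length(grid) < 1 || any(grid <= 0))
    stop("'grid' must contain positive candidate gamma values")
  grid <- sort(grid)
  w <- vapply(grid, function(g) {
    x <- ttc(concentrations, sigmoid_params(ec50 = ec50, gamma = g))
    stats::shapiro.test(x)$statistic
  }, numeric(1))
  best <- grid[which.max(w)]  # which.max takes the first max: smaller gamma wins ties
  structure(best, scores = data.frame(gamma = grid, W = unname(w)))
}

#' Concentration equivalent of a one-unit TTC increase
#'
#' The association estimates of the survival models are expressed per TTC
#' unit; this helper translates a unit step back to the concentration scale.
#' For example, with the default transform one TTC unit above 350 ng/mL is
#' about 361 ng/mL, and one unit above 600 ng/mL is about 617 ng/mL.
#'
#' @param conc Reference concentration (ng/mL); `ttc(conc) + 1` must be < 100.
#' @param params A [sigmoid_params()] object.
#' @return The concentration whose TTC is exactly one unit higher.
#' @export
unit_increase_equivalent <- function(conc, params = sigmoid_params()) {
  v <- ttc(conc, params)
  if (any(v + 1 >= params$scale))
    stop("TTC + 1 would reach the unattainable ceiling of 100")
  inverse_ttc(v + 1, params)
}

#' Solve for the gamma separating two concentrations by one TTC unit
#'
#' Given a fixed EC50, finds the steepness gamma such that
#' `ttc(conc_hi) - ttc(conc_lo) == 1`. Used to recover the transform implied
#' by a printed unit-increase concentration pair.
#'
#' @param conc_lo,conc_hi The concentration pair (ng/mL), `conc_lo < conc_hi`.
#' @param ec50 Fixed EC50 (ng/mL).
#' @return The gamma (scalar).
#' @export
gamma_from_unit_pair <- function(conc_lo, conc_hi, ec50 = 600) {
  stopifnot(conc_lo > 0, conc_hi > conc_lo)
  f <- function(g) {
    p <- sigmoid_params(ec50 = ec50, gamma = g)
    (ttc(conc_hi, p) - ttc(conc_lo, p)) - 1
  }
  stats::uniroot(f, interval = c(1e-3, 50), tol = 1e-12)$root
}

#' Augment a longitudinal PK table with trough and TTC columns
#'
#' Takes the long-format sample table (one row per plasma sample) and appends
#' the extrapolated trough (`trough_ng_ml`) and its transformed value (`ttc`).
#'
#' @param long A data frame with columns `patient_id`, `t_obs_months`,
#'   `conc_ng_ml`, `t_since_dose_h`, `dose_mg`.
#' @param params A [sigmoid_params()] object.
#' @param constants A [pk_constants()] object.
#' @return The input data frame with `trough_ng_ml` and `ttc` columns added.
#' @export
transform_troughs <- function(long, params = sigmoid_params(),
                              constants = pk_constants()) {
  need <- c("patient_id", "t_obs_months", "conc_ng_ml", "t_since_dose_h", "dose_mg")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("longitudinal table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(long$conc_ng_ml) | long$conc_ng_ml <= 0)
  if (length(bad))
    stop("non-positive concentration in rows: ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(long$t_since_dose_h) | long$t_since_dose_h < 0)
  if (length(bad))
    stop("negative time since dose in rows: ", paste(bad, collapse = ", "))
  long$trough_ng_ml <- extrapolate_trough(long$conc_ng_ml, long$t_since_dose_h,
                                          constants)
  long$ttc <- ttc(long$trough_ng_ml, params)
  long
}

# Days per month used for every time conversion in the package.
DAYS_PER_MONTH <- 30.4375
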