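# Environmental rate functions: scalar responses of larval development or
# growth rate to one environmental factor each. All functions are vectorized
# over the driving factor and return rates in the units carried by their
# maximum-rate parameter (several shipped values are normalized to 1).

#' Arrhenius temperature-response parameters
#'
#' Parameters of the Arrhenius development-rate model with low- and
#' high-temperature boundary corrections. The response is
#' \deqn{r_T(T) = k_{rrefT} \frac{e^{k_{TA}/k_{Tref} - k_{TA}/T_K}}
#'   {1 + e^{k_{TAL}/T_K - k_{TAL}/k_{TL}} + e^{k_{TAH}/k_{TH} - k_{TAH}/T_K}}}
#' with \eqn{T_K} the substrate temperature in kelvin.
#'
#' @param k_r_ref_T development rate at the reference temperature (normalized
#'   or s^-1; see `normalized`).
#' @param k_T_A,k_T_AL,k_T_AH Arrhenius temperatures for the reference, lower
#'   and upper boundary terms, in K.
#' @param k_T_ref,k_T_L,k_T_H reference, lower-boundary and upper-boundary
#'   temperatures, in K. Must satisfy `k_T_L < k_T_ref < k_T_H`.
#' @param normalized logical flag recording whether `k_r_ref_T` is on a
#'   normalized (max-1) scale rather than an absolute one.
#' @return An object of class `arrhenius_params`.
#' @seealso [arrhenius_rate()]
#' @export
arrhenius_params <- function(k_r_ref_T, k_T_A, k_T_AL, k_T_AH,
                             k_T_ref, k_T_L, k_T_H, normalized = TRUE) {
  p <- structure(
    list(k_r_ref_T = k_r_ref_T, k_T_A = k_T_A, k_T_AL = k_T_AL,
         k_T_AH = k_T_AH, k_T_ref = k_T_ref, k_T_L = k_T_L, k_T_H = k_T_H,
         normalized = isTRUE(normalized)),
    class = c("arrhenius_params", "bsf_params"))
  validate_params(p)
}

#' Modified Logan-10 temperature-response parameters
#'
#' The Logan-10 thermal performance curve describes an exponential rise of the
#' rate above a lower threshold and a shutdown near a lethal maximum. The
#' modified form used here is bounded below by zero (the unmodified model goes
#' negative above the lethal temperature):
#' \deqn{r_T(T) = k_{rmaxT}\left(1 + k_\gamma e^{-k_{\rho T}(T - k_{Tbase})}
#'   + e^{-(k_{Tmax} - T)/k_{\Delta T}}\right)^{-1}}
#' with \eqn{k_\gamma = (k_{rmaxT} - k_{rbaseT})/k_{rbaseT}}.
#'
#' @param k_r_max_T maximum rate (normalized or s^-1).
#' @param k_r_base_T rate just above the lower threshold; must be positive
#'   (it defines \eqn{k_\gamma}) and not exceed `k_r_max_T`.
#' @param k_rho_T rate change per degree Celsius (1/degC).
#' @param k_T_base lower threshold temperature (degC).
#' @param k_T_max lethal maximum temperature (degC).
#' @param k_delta_T width of the high-temperature boundary layer (degC).
#' @param normalized see [arrhenius_params()].
#' @return An object of class `logan10_params` with the derived slope
#'   `k_gamma` attached.
#' @seealso [logan10_rate()]
#' @export
logan10_params <- function(k_r_max_T, k_r_base_T, k_rho_T,
                           k_T_base, k_T_max, k_delta_T, normalized = TRUE) {
  p <- structure(
    list(k_r_max_T = k_r_max_T, k_r_base_T = k_r_base_T, k_rho_T = k_rho_T,
         k_T_base = k_T_base, k_T_max = k_T_max, k_delta_T = k_delta_T,
         normalized = isTRUE(normalized)),
    class = c("logan10_params", "bsf_params"))
  validate_params(p)
  p$k_gamma <- (p$k_r_max_T - p$k_r_base_T) / p$k_r_base_T
  p
}

#' Monod (type-II) saturation parameters
#'
#' Saturating rate law `r_max * x / (x + k_half)` used for the development and
#' growth responses to feed density and for the growth response to airflow.
#'
#' @param r_max maximum rate, in the units of the response.
#' @param k_half half-saturation value of the driving factor (its units).
#' @param normalized see [arrhenius_params()].
#' @return An object of class `monod_params`.
#' @seealso [monod_rate()]
#' @export
monod_params <- function(r_max, k_half, normalized = FALSE) {
  p <- structure(list(r_max = r_max, k_half = k_half,
                      normalized = isTRUE(normalized)),
                 class = c("monod_params", "bsf_params"))
  validate_params(p)
}

#' Substrate-moisture response parameters
#'
#' Thresholds of the piecewise moisture response (kg water per kg wet
#' substrate): assimilation is impossible below `k_W_med_C1`, ramps up
#' linearly to `k_W_med_C2`, and is unconstrained above it; respiration is
#' unconstrained below `k_W_med_C3`, declines linearly and ceases at
#' `k_W_med_crit` (larvae drown above it).
#'
#' @param k_r_max_W maximum growth rate in response to moisture (normalized or
#'   absolute).
#' @param k_W_med_C1,k_W_med_C2,k_W_med_C3,k_W_med_crit ordered moisture
#'   thresholds in kg/kg wet basis, all in `[0, 1]`.
#' @param normalized see [arrhenius_params()].
#' @return An object of class `moisture_params`.
#' @seealso [moisture_growth_rate()]
#' @export
moisture_params <- function(k_r_max_W, k_W_med_C1, k_W_med_C2,
                            k_W_med_C3, k_W_med_crit, normalized = TRUE) {
  p <- structure(
    list(k_r_max_W = k_r_max_W, k_W_med_C1 = k_W_med_C1,
         k_W_med_C2 = k_W_med_C2, k_W_med_C3 = k_W_med_C3,
         k_W_med_crit = k_W_med_crit, normalized = isTRUE(normalized)),
    class = c("moisture_params", "bsf_params"))
  validate_params(p)
}

#' Logistic airflow-response parameters
#'
#' Parameters of the logistic airflow model
#' `k_r_max_A / (1 + exp((A - k_A_inf) / k_A_trans))`, implemented exactly as
#' written. Note that with `k_A_trans > 0` the curve *decreases* with airflow;
#' a growth response that saturates with increasing aeration requires a
#' negative `k_A_trans`. The sign convention is left to the caller because the
#' alternative Monod airflow model (a [monod_params()] instance) is the
#' default in shipped profiles.
#'
#' @param k_r_max_A maximum rate.
#' @param k_A_inf inflection airflow (l/min).
#' @param k_A_trans transition slope (l/min); nonzero, negative for an
#'   increasing response.
#' @param normalized see [arrhenius_params()].
#' @return An object of class `airflow_logistic_params`.
#' @seealso [airflow_logistic_rate()]
#' @export
airflow_logistic_params <- function(k_r_max_A, k_A_inf, k_A_trans,
                                    normalized = TRUE) {
  p <- structure(
    list(k_r_max_A = k_r_max_A, k_A_inf = k_A_inf, k_A_trans = k_A_trans,
         normalized = isTRUE(normalized)),
    class = c("airflow_logistic_params", "bsf_params"))
  validate_params(p)
}

#' Validate a parameter object
#'
#' Checks the structural invariants of a parameter object (positivity,
#' ordering of thresholds, ...) and returns it invisibly, or signals an error
#' naming the offending field.
#'
#' @param p a parameter object created by one of the `*_params()`
#'   constructors.
#' @return `p`, invisibly for side-effect use, visibly from constructors.
#' @export
validate_params <- function(p) UseMethod("validate_params")

#' @export
validate_params.arrhenius_params <- function(p) {
  for (f in c("k_r_ref_T", "k_T_A", "k_T_AL", "k_T_AH",
              "k_T_ref", "k_T_L", "k_T_H")) {
    .check(.is_num1(p[[f]]), "arrhenius_params: ", f,
           " must be a single finite number")
  }
  .check(p$k_T_ref > 0 && p$k_T_L > 0 && p$k_T_H > 0,
         "arrhenius_params: boundary temperatures must be positive (kelvin)")
  .check(p$k_T_L < p$k_T_ref && p$k_T_ref < p$k_T_H,
         "arrhenius_params: require k_T_L < k_T_ref < k_T_H")
  .check(p$k_r_ref_T >= 0, "arrhenius_params: k_r_ref_T must be >= 0")
  p
}

#' @export
validate_params.logan10_params <- function(p) {
  for (f in c("k_r_max_T", "k_r_base_T", "k_rho_T",
              "k_T_base", "k_T_max", "k_delta_T")) {
    .check(.is_num1(p[[f]]), "logan10_params: ", f,
           " must be a single finite number")
  }
  .check(p$k_r_base_T > 0,
         "logan10_params: k_r_base_T must be > 0 (k_gamma undefined at 0)")
  .check(p$k_r_base_T <= p$k_r_max_T,
         "logan10_params: require k_r_base_T <= k_r_max_T")
  .check(p$k_T_base < p$k_T_max,
         "logan10_params: require k_T_base < k_T_max")
  .check(p$k_delta_T > 0, "logan10_params: k_delta_T must be > 0")
  .check(p$k_rho_T > 0, "logan10_params: k_rho_T must be > 0")
  p
}

#' @export
validate_params.monod_params <- function(p) {
  .check(.is_num1(p$r_max) && p$r_max >= 0,
         "monod_params: r_max must be a single number >= 0")
  .check(.is_num1(p$k_half) && p$k_half > 0,
         "monod_params: k_half must be a single number > 0")
  p
}

#' @export
validate_params.moisture_params <- function(p) {
  for (f in c("k_r_max_W", "k_W_med_C1", "k_W_med_C2",
              "k_W_med_C3", "k_W_med_crit")) {
    .check(.is_num1(p[[f]]), "moisture_params: ", f,
           " must be a single finite number")
  }
  .check(p$k_r_max_W >= 0, "moisture_params: k_r_max_W must be >= 0")
  .check(p$k_W_med_C1 >= 0 && p$k_W_med_crit <= 1,
         "moisture_params: thresholds must lie in [0, 1]")
  .check(p$k_W_med_C1 < p$k_W_med_C2 && p$k_W_med_C2 <= p$k_W_med_C3 &&
           p$k_W_med_C3 < p$k_W_med_crit,
         "moisture_params: require k_W_med_C1 < k_W_med_C2 <= k_W_med_C3 < ",
         "k_W_med_crit")
  p
}

#' @export
validate_params.airflow_logistic_params <- function(p) {
  .check(.is_num1(p$k_r_max_A) && p$k_r_max_A >= 0,
         "airflow_logistic_params: k_r_max_A must be >= 0")
  .check(.is_num1(p$k_A_inf), "airflow_logistic_params: k_A_inf must be a ",
         "single finite number")
  .check(.is_num1(p$k_A_trans) && p$k_A_trans != 0,
         "airflow_logistic_params: k_A_trans must be nonzero")
  p
}

#' Arrhenius development rate with boundary corrections
#'
#' @param T_med substrate temperature in degrees Celsius (vectorized).
#' @param p an [arrhenius_params()] object.
#' @return Development rate(s) in the units of `p$k_r_ref_T`. Finite for any
#'   representable temperature (exponents are capped before exponentiation).
#' @examples
#' p <- load_profile("table3_original")$arrhenius
#' arrhenius_rate(25.77, p)   # ~0.711, damped only by the boundary terms
#' @export
arrhenius_rate <- function(T_med, p) {
  validate_params(p)
  .check(is.numeric(T_med) && all(T_med > -273.15),
         "T_med must be above absolute zero (-273.15 degC)")
  T_K <- T_med + 273.15
  num <- .exp_clamped(p$k_T_A / p$k_T_ref - p$k_T_A / T_K)
  den <- 1 +
    .exp_clamped(p$k_T_AL / T_K - p$k_T_AL / p$k_T_L) +
    .exp_clamped(p$k_T_AH / p$k_T_H - p$k_T_AH / T_K)
  p$k_r_ref_T * num / den
}

#' Modified Logan-10 development rate
#'
#' @param T_med substrate temperature in degrees Celsius (vectorized).
#' @param p a [logan10_params()] object.
#' @return Rate(s) in `[0, k_r_max_T]`; tends to zero (never negative) for
#'   temperatures far above the lethal maximum.
#' @examples
#' p <- load_profile("table3_original")$logan10
#' logan10_rate(30, p)   # ~0.87 on the normalized scale
#' @export
logan10_rate <- function(T_med, p) {
  validate_params(p)
  .check(is.numeric(T_med), "T_med must be numeric")
  k_gamma <- (p$k_r_max_T - p$k_r_base_T) / p$k_r_base_T
  den <- 1 +
    k_gamma * .exp_clamped(-p$k_rho_T * (T_med - p$k_T_base)) +
    .exp_clamped(-(p$k_T_max - T_med) / p$k_delta_T)
  p$k_r_max_T / den
}

#' Monod saturation rate
#'
#' @param x driving factor value(s), nonnegative (feed density in g/d per
#'   larva, or airflow in l/min).
#' @param p a [monod_params()] object.
#' @return `r_max * x / (x + k_half)`: zero at `x = 0`, exactly `r_max / 2` at
#'   `x = k_half`, strictly increasing and bounded by `r_max`.
#' @export
monod_rate <- function(x, p) {
  validate_params(p)
  .check(is.numeric(x) && all(x >= 0), "x must be numeric and >= 0")
  # written as r_max / (1 + k_half/x) so that the half-saturation identity
  # monod_rate(k_half) == r_max / 2 holds exactly in floating point
  ifelse(x == 0, 0, p$r_max / (1 + p$k_half / x))
}

#' Moisture limitation of assimilation
#'
#' Piecewise factor in `[0, 1]`: 0 at or below `k_W_med_C1`, a linear ramp up
#' to `k_W_med_C2`, and 1 above. With `smooth = TRUE` the ramp is replaced by
#' an ascending logistic with slope `4 / ramp width` centred on the ramp
#' midpoint (the same convention used for all smoothed switches in the ODE).
#'
#' @param W substrate moisture, kg water per kg wet substrate, in `[0, 1]`
#'   (vectorized).
#' @param p a [moisture_params()] object.
#' @param smooth logical; use the logistic replacement of the ramp.
#' @return Factor(s) in `[0, 1]`.
#' @export
moisture_assim_factor <- function(W, p, smooth = FALSE) {
  validate_params(p)
  .check(is.numeric(W) && all(W >= 0 & W <= 1), "W must lie in [0, 1]")
  c1 <- p$k_W_med_C1
  c2 <- p$k_W_med_C2
  if (smooth) {
    smooth_step(W, x0 = (c1 + c2) / 2, k = 4 / (c2 - c1),
                direction = "ascending")
  } else {
    f <- (W - c1) / (c2 - c1)
    pmin(pmax(f, 0), 1)
  }
}

#' Moisture limitation of respiration
#'
#' Piecewise factor in `[0, 1]`: 1 at or below `k_W_med_C3` (gas exchange
#' unconstrained), linear descent `(W - k_W_med_crit)/(k_W_med_C3 -
#' k_W_med_crit)` between `k_W_med_C3` and `k_W_med_crit`, 0 above (larvae
#' drown). Smoothing as in [moisture_assim_factor()], descending.
#'
#' @inheritParams moisture_assim_factor
#' @return Factor(s) in `[0, 1]`.
#' @export
moisture_resp_factor <- function(W, p, smooth = FALSE) {
  validate_params(p)
  .check(is.numeric(W) && all(W >= 0 & W <= 1), "W must lie in [0, 1]")
  c3 <- p$k_W_med_C3
  cc <- p$k_W_med_crit
  if (smooth) {
    smooth_step(W, x0 = (c3 + cc) / 2, k = 4 / (cc - c3),
                direction = "descending")
  } else {
    f <- (W - cc) / (c3 - cc)
    pmin(pmax(f, 0), 1)
  }
}

#' Growth rate in response to substrate moisture
#'
#' Product `k_r_max_W * assimilation factor * respiration factor`; zero
#' outside the interval `(k_W_med_C1, k_W_med_crit)` and maximal on the
#' plateau `[k_W_med_C2, k_W_med_C3]` (piecewise mode).
#'
#' @inheritParams moisture_assim_factor
#' @return Rate(s) in the units of `k_r_max_W`.
#' @export
moisture_growth_rate <- function(W, p, smooth = FALSE) {
  p$k_r_max_W * moisture_assim_factor(W, p, smooth) *
    moisture_resp_factor(W, p, smooth)
}

#' Logistic growth response to airflow
#'
#' Evaluates `k_r_max_A * (1 + exp((A - k_A_inf)/k_A_trans))^-1` exactly as
#' written; see [airflow_logistic_params()] for the sign convention.
#'
#' @param A airflow rate, l/min, nonnegative (vectorized).
#' @param p an [airflow_logistic_params()] object.
#' @return Rate(s) in `[0, k_r_max_A]`; equals `k_r_max_A / 2` at the
#'   inflection airflow.
#' @export
airflow_logistic_rate <- function(A, p) {
  validate_params(p)
  .check(is.numeric(A) && all(A >= 0), "A must be numeric and >= 0")
  p$k_r_max_A / (1 + .exp_clamped((A - p$k_A_inf) / p$k_A_trans))
}
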