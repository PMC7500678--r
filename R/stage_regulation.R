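# Stage-dependent regulation: how the development sum throttles assimilation
# and maturity-maintenance, logistic smoothing of switching behaviour, and
# the combined (multiplicative) regulators used by the ODE right-hand side.

#' Logistic smoothing step
#'
#' The sigmoid `1 / (1 + exp(-k (x - x0)))` (or its complement for a
#' descending switch) used throughout the package to replace piecewise
#' switches by smooth transitions, so that the ODE right-hand side stays
#' differentiable and adaptive solvers converge. The package-wide slope
#' convention is `k = 4 / width`, with the midpoint at the centre of the ramp
#' being smoothed: the logistic then matches the ramp slope at its midpoint.
#'
#' @param x input value(s).
#' @param x0 transition midpoint, where the step equals 0.5.
#' @param k logistic slope (1 / input units), must be positive.
#' @param direction `"ascending"` (0 to 1) or `"descending"` (1 to 0).
#' @return Value(s) in `(0, 1)`, continuous and monotone in `x`.
#' @examples
#' smooth_step(0, 0, 4)            # 0.5 at the midpoint
#' smooth_step(2 / 4 + 0, 0, 4)    # 1/(1 + e^-2)
#' @export
smooth_step <- function(x, x0, k, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  .check(.is_num1(x0), "smooth_step: x0 must be a single finite number")
  .check(.is_num1(k) && k > 0, "smooth_step: k must be a single number > 0")
  f <- 1 / (1 + .exp_clamped(-k * (x - x0)))
  if (direction == "descending") 1 - f else f
}

#' Development-stage parameters
#'
#' Development-sum milestones and the asymptotic dry mass that together
#' regulate assimilation and maturation over the larval life cycle.
#' `k_T_sum_1` marks the development point at which assimilation starts to
#' cease, `k_T_sum_2` the end of feeding, and `k_T_sum_3` the end of the
#' (pre)pupal development phase. `w_mat` is the smoothing width used for the
#' otherwise zero-width maturity switch at `k_T_sum_3`.
#'
#' @param k_T_sum_1,k_T_sum_2,k_T_sum_3 ordered development-sum milestones, h.
#' @param k_B_asy asymptotic dry mass under unlimited feeding, g.
#' @param w_mat smoothing width of the maturity switch, h (> 0).
#' @return An object of class `stage_params` with the derived assimilation
#'   switch midpoint `k_T_sum_inf = k_T_sum_1 + 0.5 (k_T_sum_2 - k_T_sum_1)`.
#' @export
stage_params <- function(k_T_sum_1, k_T_sum_2, k_T_sum_3, k_B_asy,
                         w_mat = 10) {
  p <- structure(
    list(k_T_sum_1 = k_T_sum_1, k_T_sum_2 = k_T_sum_2,
         k_T_sum_3 = k_T_sum_3, k_B_asy = k_B_asy, w_mat = w_mat),
    class = c("stage_params", "bsf_params"))
  validate_params(p)
  p$k_T_sum_inf <- p$k_T_sum_1 + 0.5 * (p$k_T_sum_2 - p$k_T_sum_1)
  p
}

#' @export
validate_params.stage_params <- function(p) {
  for (f in c("k_T_sum_1", "k_T_sum_2", "k_T_sum_3", "k_B_asy", "w_mat")) {
    .check(.is_num1(p[[f]]), "stage_params: ", f,
           " must be a single finite number")
  }
  .check(0 < p$k_T_sum_1 && p$k_T_sum_1 < p$k_T_sum_2 &&
           p$k_T_sum_2 < p$k_T_sum_3,
         "stage_params: require 0 < k_T_sum_1 < k_T_sum_2 < k_T_sum_3")
  .check(p$k_B_asy > 0, "stage_params: k_B_asy must be > 0")
  .check(p$w_mat > 0, "stage_params: w_mat must be > 0")
  p
}

#' Ingestion potential of a larva
#'
#' Size throttle on ingestion: `1 - B_dry / k_B_asy`, the feeding potential
#' relative to the asymptotic dry mass, floored at zero for larvae at or above
#' the asymptote (negative assimilation is biologically meaningless and would
#' destabilize the ODE).
#'
#' @param B_dry larval dry mass, g, nonnegative (vectorized).
#' @param p a [stage_params()] object.
#' @return Factor(s) in `[0, 1]` for `B_dry` in `[0, k_B_asy]`.
#' @export
ingestion_potential <- function(B_dry, p) {
  .check(is.numeric(B_dry) && all(B_dry >= 0), "B_dry must be >= 0")
  pmax(1 - B_dry / p$k_B_asy, 0)
}

#' Stage-dependent assimilation factor
#'
#' Assimilation over the development sum: full ingestion potential before
#' `k_T_sum_1`, a linear ramp down to zero at `k_T_sum_2`, zero afterwards.
#' The smoothed form multiplies the ingestion potential by a descending
#' logistic with slope `4 / (k_T_sum_2 - k_T_sum_1)` and midpoint
#' `k_T_sum_inf`; the multiplicative ingestion potential is retained so the
#' asymptotic-size throttle is not lost in the smoothed model.
#'
#' @param T_sum development sum, h, nonnegative (vectorized).
#' @param B_dry larval dry mass, g (vectorized or scalar).
#' @param p a [stage_params()] object.
#' @param smooth logical; use the logistic switch.
#' @return Factor(s) in `[0, 1]`.
#' @export
assim_stage_factor <- function(T_sum, B_dry, p, smooth = FALSE) {
  .check(is.numeric(T_sum) && all(T_sum >= 0), "T_sum must be >= 0")
  pot <- ingestion_potential(B_dry, p)
  if (smooth) {
    sw <- smooth_step(T_sum, x0 = p$k_T_sum_inf,
                      k = 4 / (p$k_T_sum_2 - p$k_T_sum_1),
                      direction = "descending")
    return(pot * sw)
  }
  ramp <- (T_sum - p$k_T_sum_2) / (p$k_T_sum_1 - p$k_T_sum_2)
  pot * pmin(pmax(ramp, 0), 1)
}

#' Stage-dependent maturity-maintenance factor
#'
#' Maturity allocation continues at full rate until the development sum
#' reaches `k_T_sum_3` (end of the prepupal stage) and ceases afterwards.
#' The smoothed form is a descending logistic with midpoint `k_T_sum_3` and
#' slope `4 / w_mat`.
#'
#' @inheritParams assim_stage_factor
#' @return Factor(s) in `[0, 1]`.
#' @export
maturity_stage_factor <- function(T_sum, p, smooth = FALSE) {
  .check(is.numeric(T_sum) && all(T_sum >= 0), "T_sum must be >= 0")
  if (smooth) {
    smooth_step(T_sum, x0 = p$k_T_sum_3, k = 4 / p$w_mat,
                direction = "descending")
  } else {
    as.numeric(T_sum < p$k_T_sum_3)
  }
}

# --- normalized single-factor regulators ------------------------------------

# Each helper returns a dimensionless factor in [0, 1]: the rate function
# divided by its own maximum-rate parameter, so that normalized and absolute
# parameter profiles behave identically inside the combined regulators.

#' Normalized temperature factor
#'
#' Temperature response divided by its maximum, as used inside the combined
#' regulators. Which thermal model is used is set by
#' `profile$temperature_model` (`"logan10"`, the default, or `"arrhenius"`).
#' The Logan-10 response is normalized by its `k_r_max_T` parameter; the
#' Arrhenius response has no explicit maximum-rate parameter, so it is
#' normalized by its numerically located maximum over a wide rearing range
#' (cached on the profile by [parameter_profile()]).
#'
#' @param T_med substrate temperature, degC (vectorized).
#' @param profile a [parameter_profile()].
#' @return Factor(s) in `[0, 1]`.
#' @export
temperature_factor <- function(T_med, profile) {
  if (identical(profile$temperature_model, "arrhenius")) {
    mx <- profile$arrhenius_max
    .check(.is_num1(mx) && mx > 0,
           "profile: cached Arrhenius maximum missing or zero")
    pmin(arrhenius_rate(T_med, profile$arrhenius) / mx, 1)
  } else {
    p <- profile$logan10
    .check(p$k_r_max_T > 0, "logan10: k_r_max_T must be > 0 to normalize")
    logan10_rate(T_med, p) / p$k_r_max_T
  }
}

.feed_factor <- function(B_feed, mp) {
  .check(mp$r_max > 0, "monod: r_max must be > 0 to normalize")
  monod_rate(B_feed, mp) / mp$r_max
}

.airflow_factor <- function(A_air, profile) {
  if (identical(profile$airflow_model, "logistic")) {
    p <- profile$airflow_logistic
    .check(!is.null(p), "profile: airflow_model is 'logistic' but no ",
           "airflow_logistic parameters are present")
    .check(p$k_r_max_A > 0, "airflow_logistic: k_r_max_A must be > 0")
    airflow_logistic_rate(A_air, p) / p$k_r_max_A
  } else {
    .feed_factor(A_air, profile$airflow_monod)
  }
}

.moisture_factor <- function(W, profile, smooth) {
  moisture_assim_factor(W, profile$moisture, smooth) *
    moisture_resp_factor(W, profile$moisture, smooth)
}

#' Combined assimilation regulator
#'
#' The valve on the ingestion flux: the stage-dependent assimilation factor
#' times the normalized temperature, feed-growth, moisture and airflow
#' factors. Each factor lies in `[0, 1]`, hence so does the product; any
#' single exhausted resource annihilates assimilation.
#'
#' @param T_sum development sum, h.
#' @param B_dry larval dry mass, g.
#' @param env an [env_state()].
#' @param profile a [parameter_profile()].
#' @param smooth logical; smoothed switching functions (the form used inside
#'   the ODE).
#' @return Scalar regulator in `[0, 1]`.
#' @export
combined_assim_regulator <- function(T_sum, B_dry, env, profile,
                                     smooth = TRUE) {
  assim_stage_factor(T_sum, B_dry, profile$stage, smooth) *
    temperature_factor(env$T_med, profile) *
    .feed_factor(env$B_feed, profile$monod_grw) *
    .moisture_factor(env$W_med_pct, profile, smooth) *
    .airflow_factor(env$A_air, profile)
}

#' Combined maturity-maintenance regulator
#'
#' The valve on the maturity-maintenance flux: stage factor times the
#' normalized temperature, feed-growth and airflow factors. Moisture is
#' absent here: maintenance metabolism is not limited by substrate moisture
#' in this model.
#'
#' @inheritParams combined_assim_regulator
#' @return Scalar regulator in `[0, 1]`.
#' @export
combined_mat_regulator <- function(T_sum, env, profile, smooth = TRUE) {
  maturity_stage_factor(T_sum, profile$stage, smooth) *
    temperature_factor(env$T_med, profile) *
    .feed_factor(env$B_feed, profile$monod_grw) *
    .airflow_factor(env$A_air, profile)
}

#' Combined development regulator
#'
#' The rate at which the development sum accumulates, relative to its
#' maximum: the product of the normalized temperature, feed-development
#' (the development Monod instance, not the growth one), moisture and airflow
#' factors. Independent of the larval state.
#'
#' @inheritParams combined_assim_regulator
#' @return Scalar regulator in `[0, 1]`.
#' @export
combined_dev_regulator <- function(env, profile, smooth = TRUE) {
  temperature_factor(env$T_med, profile) *
    .feed_factor(env$B_feed, profile$monod_dev) *
    .moisture_factor(env$W_med_pct, profile, smooth) *
    .airflow_factor(env$A_air, profile)
}
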