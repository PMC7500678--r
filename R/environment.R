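# Environmental state and time-varying environment schedules.

#' Environmental state
#'
#' A snapshot of the four environmental drivers of larval growth and
#' development.
#'
#' @param T_med substrate temperature, degC.
#' @param B_feed feed availability, g dry feed per day per larva, >= 0.
#' @param W_med_pct substrate moisture, kg water per kg wet substrate, in
#'   `[0, 1]`.
#' @param A_air airflow rate, l/min, >= 0.
#' @return An object of class `env_state`.
#' @export
env_state <- function(T_med, B_feed, W_med_pct, A_air) {
  e <- structure(list(T_med = T_med, B_feed = B_feed,
                      W_med_pct = W_med_pct, A_air = A_air),
                 class = "env_state")
  for (f in c("T_med", "B_feed", "W_med_pct", "A_air")) {
    .check(.is_num1(e[[f]]), "env_state: ", f,
           " must be a single finite number")
  }
  .check(e$T_med > -273.15, "env_state: T_med must be above absolute zero")
  .check(e$B_feed >= 0, "env_state: B_feed must be >= 0")
  .check(e$W_med_pct >= 0 && e$W_med_pct <= 1,
         "env_state: W_med_pct must lie in [0, 1]")
  .check(e$A_air >= 0, "env_state: A_air must be >= 0")
  e
}

#' Favourable rearing conditions
#'
#' A constant environment near the optimum of every static response for the
#' given profile: temperature at the maximum of the active thermal model,
#' moisture at the centre of the moisture plateau, and configurable feed
#' ration and airflow. The default ration of 0.1 g/d per larva is at the
#' upper end of the feeding-rate ranges reported for rearing experiments;
#' feed-unlimited conditions can be emulated by passing a large `B_feed`.
#'
#' @param profile a [parameter_profile()].
#' @param B_feed feed ration, g/d per larva.
#' @param A_air airflow rate, l/min.
#' @return An [env_state()].
#' @export
reference_env <- function(profile, B_feed = 0.1, A_air = 2) {
  tm <- if (identical(profile$temperature_model, "arrhenius")) {
    function(x) arrhenius_rate(x, profile$arrhenius)
  } else {
    function(x) logan10_rate(x, profile$logan10)
  }
  T_opt <- optimize(tm, c(0, 60), maximum = TRUE)$maximum
  W_opt <- (profile$moisture$k_W_med_C2 + profile$moisture$k_W_med_C3) / 2
  env_state(T_med = T_opt, B_feed = B_feed, W_med_pct = W_opt, A_air = A_air)
}

#' Environment schedule
#'
#' A time-stamped sequence of environmental states with strictly increasing
#' times. Between samples the environment is held constant at the most recent
#' sample (zero-order hold, matching experiments in which conditions are held
#' piecewise constant); linear interpolation is available via `env_at()`.
#'
#' @param time_h sample times, hours, strictly increasing, nonempty.
#' @param T_med,B_feed,W_med_pct,A_air driver values at the sample times;
#'   scalars are recycled. Units as in [env_state()].
#' @return An object of class `environment_schedule` wrapping a data frame
#'   with columns `time_h`, `T_med_C`, `B_feed_g_d`, `W_med_pct`,
#'   `A_air_l_min`.
#' @export
environment_schedule <- function(time_h, T_med, B_feed, W_med_pct, A_air) {
  .check(is.numeric(time_h) && length(time_h) >= 1L && all(is.finite(time_h)),
         "environment_schedule: time_h must be nonempty and finite")
  .check(length(time_h) == 1L || all(diff(time_h) > 0),
         "environment_schedule: time stamps must be strictly increasing")
  df <- data.frame(time_h = time_h, T_med_C = T_med, B_feed_g_d = B_feed,
                   W_med_pct = W_med_pct, A_air_l_min = A_air)
  for (i in seq_len(nrow(df))) {
    env_state(df$T_med_C[i], df$B_feed_g_d[i], df$W_med_pct[i],
              df$A_air_l_min[i])  # validates each row
  }
  structure(list(data = df), class = "environment_schedule")
}

#' Constant schedule from a single state
#' @param env an [env_state()].
#' @return A one-row [environment_schedule()].
#' @export
as_schedule <- function(env) {
  if (inherits(env, "environment_schedule")) return(env)
  .check(inherits(env, "env_state"),
         "env must be an env_state or environment_schedule")
  environment_schedule(0, env$T_med, env$B_feed, env$W_med_pct, env$A_air)
}

#' Environment at a given time
#'
#' @param schedule an [environment_schedule()] (or [env_state()], treated as
#'   constant).
#' @param t_h query time, hours. Times before the first sample return the
#'   first sample; times after the last return the last (hold extrapolation).
#' @param interpolation `"hold"` (default) or `"linear"`.
#' @return An [env_state()].
#' @export
env_at <- function(schedule, t_h, interpolation = c("hold", "linear")) {
  interpolation <- match.arg(interpolation)
  schedule <- as_schedule(schedule)
  df <- schedule$data
  n <- nrow(df)
  i <- findInterval(t_h, df$time_h, rightmost.closed = FALSE)
  i <- max(i, 1L)
  if (interpolation == "hold" || i >= n || t_h <= df$time_h[1]) {
    row <- df[min(i, n), ]
    return(env_state(row$T_med_C, row$B_feed_g_d, row$W_med_pct,
                     row$A_air_l_min))
  }
  w <- (t_h - df$time_h[i]) / (df$time_h[i + 1] - df$time_h[i])
  lerp <- function(col) (1 - w) * df[[col]][i] + w * df[[col]][i + 1]
  env_state(lerp("T_med_C"), lerp("B_feed_g_d"), lerp("W_med_pct"),
            lerp("A_air_l_min"))
}
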