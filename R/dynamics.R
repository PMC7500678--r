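# The two-state dynamic model: regulated dry-mass balance and development
# sum, flux partitioning, adaptive ODE simulation over environment schedules,
# and stage-event detection.

#' Instantaneous regulators
#'
#' Evaluates the three combined regulators at one state/environment point,
#' honouring optional constant overrides (used to exercise the closed-form
#' behaviour of the mass balance in tests).
#'
#' @param T_sum development sum, h.
#' @param B_dry dry mass, g.
#' @param env an [env_state()].
#' @param profile a [parameter_profile()].
#' @param smooth logical; smoothed switching functions.
#' @param overrides optional named list with any of `r_assim`, `r_mat`,
#'   `r_dev` as fixed numbers.
#' @return Named list `r_assim`, `r_mat`, `r_dev`.
#' @export
regulators_at <- function(T_sum, B_dry, env, profile, smooth = TRUE,
                          overrides = NULL) {
  r <- list(
    r_assim = combined_assim_regulator(T_sum, B_dry, env, profile, smooth),
    r_mat = combined_mat_regulator(T_sum, env, profile, smooth),
    r_dev = combined_dev_regulator(env, profile, smooth))
  if (!is.null(overrides)) r[names(overrides)] <- overrides
  r
}

#' Right-hand side of the growth and development ODEs
#'
#' The dry-mass balance
#' \deqn{dB_{dry}/dt = \epsilon_{inges} r_{assim} k_{inges} B_{dry}
#'   - r_{mat} k_{maint} B_{dry}}
#' and the development sum \eqn{dT_\Sigma/dt = r_{dev} k_{devts}}, evaluated
#' at one point. Rates are per second (the units of `k_inges`/`k_maint`);
#' [simulate_larva()] integrates them over hours.
#'
#' @inheritParams regulators_at
#' @return Named numeric vector `c(dB_dry_dt, dT_sum_dt)` in g/s and h/s;
#'   the development component is always nonnegative.
#' @export
growth_rhs <- function(T_sum, B_dry, env, profile, smooth = TRUE,
                       overrides = NULL) {
  .check(is.numeric(B_dry) && B_dry >= 0, "B_dry must be >= 0")
  r <- regulators_at(T_sum, B_dry, env, profile, smooth, overrides)
  g <- profile$growth
  c(dB_dry_dt = (g$epsilon_inges * r$r_assim * g$k_inges -
                   r$r_mat * g$k_maint) * B_dry,
    dT_sum_dt = r$r_dev * g$k_dev_ts)
}

#' Partition the ingestion flux
#'
#' Mass-balance breakdown of the instantaneous fluxes (all g/s): ingested
#' feed `phi_B_ing = r_assim k_inges B_dry`, its excreted and
#' digestion-cost parts (`k_alpha_excr`, `k_alpha_assim` fractions), the
#' effective assimilate flux `phi_B_eff = (1 - k_alpha_excr -
#' k_alpha_assim) phi_B_ing`, the combined maturity-maintenance drain
#' `phi_B_mat_maint = r_mat k_maint B_dry`, and the total metabolic
#' expenditure `phi_B_metab = phi_B_assim + phi_B_mat_maint`. By
#' construction `phi_B_ing = phi_B_excr + phi_B_assim + phi_B_eff`.
#'
#' @inheritParams regulators_at
#' @return Named list of the six fluxes.
#' @export
flux_partition <- function(T_sum, B_dry, env, profile, smooth = TRUE,
                           overrides = NULL) {
  r <- regulators_at(T_sum, B_dry, env, profile, smooth, overrides)
  g <- profile$growth
  phi_ing <- r$r_assim * g$k_inges * B_dry
  phi_excr <- g$k_alpha_excr * phi_ing
  phi_assim <- g$k_alpha_assim * phi_ing
  phi_eff <- (1 - g$k_alpha_excr - g$k_alpha_assim) * phi_ing
  phi_mat_maint <- r$r_mat * g$k_maint * B_dry
  list(phi_B_ing = phi_ing, phi_B_excr = phi_excr, phi_B_assim = phi_assim,
       phi_B_eff = phi_eff, phi_B_mat_maint = phi_mat_maint,
       phi_B_metab = phi_assim + phi_mat_maint)
}

# Build a fast RHS closure: environment factors are precomputed per schedule
# segment (they do not depend on the state), so each call only evaluates the
# stage switches and the mass balance.
.make_rhs <- function(profile, schedule, smooth, interpolation, overrides) {
  g <- profile$growth
  st <- profile$stage
  k_inges <- g$k_inges
  k_maint <- g$k_maint
  eps <- g$epsilon_inges
  k_dev_ts <- g$k_dev_ts
  k_B_asy <- st$k_B_asy
  T1 <- st$k_T_sum_1
  T2 <- st$k_T_sum_2
  T3 <- st$k_T_sum_3
  Tinf <- st$k_T_sum_inf
  ka <- 4 / (T2 - T1)
  km <- 4 / st$w_mat
  ov_assim <- overrides$r_assim
  ov_mat <- overrides$r_mat
  ov_dev <- overrides$r_dev

  env_factors <- function(env) {
    fT <- temperature_factor(env$T_med, profile)
    fFg <- .feed_factor(env$B_feed, profile$monod_grw)
    fFd <- .feed_factor(env$B_feed, profile$monod_dev)
    fW <- .moisture_factor(env$W_med_pct, profile, smooth)
    fA <- .airflow_factor(env$A_air, profile)
    c(assim = fT * fFg * fW * fA, mat = fT * fFg * fA,
      dev = fT * fFd * fW * fA)
  }

  sched_df <- schedule$data
  n_seg <- nrow(sched_df)
  seg_times <- sched_df$time_h
  if (interpolation == "hold") {
    seg_fac <- t(vapply(seq_len(n_seg), function(i) {
      env_factors(env_state(sched_df$T_med_C[i], sched_df$B_feed_g_d[i],
                            sched_df$W_med_pct[i], sched_df$A_air_l_min[i]))
    }, numeric(3)))
    if (n_seg == 1L) {
      fac1 <- seg_fac[1L, ]
      get_fac <- function(t) fac1
    } else {
      get_fac <- function(t) {
        i <- findInterval(t, seg_times)
        seg_fac[max(min(i, n_seg), 1L), ]
      }
    }
  } else {
    get_fac <- function(t) env_factors(env_at(schedule, t, "linear"))
  }

  cap <- .EXP_CAP
  function(t, y, parms) {
    B <- max(y[1], 0)
    Ts <- max(y[2], 0)
    fac <- get_fac(t)
    pot <- max(1 - B / k_B_asy, 0)
    if (smooth) {
      stage_a <- pot / (1 + exp(min(ka * (Ts - Tinf), cap)))
      stage_m <- 1 / (1 + exp(min(km * (Ts - T3), cap)))
    } else {
      stage_a <- pot * min(max((Ts - T2) / (T1 - T2), 0), 1)
      stage_m <- as.numeric(Ts < T3)
    }
    r_assim <- if (is.null(ov_assim)) stage_a * fac[[1L]] else ov_assim
    r_mat <- if (is.null(ov_mat)) stage_m * fac[[2L]] else ov_mat
    r_dev <- if (is.null(ov_dev)) fac[[3L]] else ov_dev
    # per-hour derivatives (rates are per second)
    list(c((eps * r_assim * k_inges - r_mat * k_maint) * B * 3600,
           r_dev * k_dev_ts * 3600))
  }
}

# Vectorized recomputation of regulators and fluxes on the output grid.
.annotate_trajectory <- function(times, B, T_sum, profile, schedule, smooth,
                                 interpolation, overrides) {
  df <- schedule$data
  if (interpolation == "hold") {
    i <- pmax(pmin(findInterval(times, df$time_h), nrow(df)), 1L)
    T_med <- df$T_med_C[i]
    B_feed <- df$B_feed_g_d[i]
    W <- df$W_med_pct[i]
    A <- df$A_air_l_min[i]
  } else {
    ee <- lapply(times, function(t) env_at(schedule, t, "linear"))
    T_med <- vapply(ee, `[[`, numeric(1), "T_med")
    B_feed <- vapply(ee, `[[`, numeric(1), "B_feed")
    W <- vapply(ee, `[[`, numeric(1), "W_med_pct")
    A <- vapply(ee, `[[`, numeric(1), "A_air")
  }
  fT <- temperature_factor(T_med, profile)
  fFg <- monod_rate(B_feed, profile$monod_grw) / profile$monod_grw$r_max
  fFd <- monod_rate(B_feed, profile$monod_dev) / profile$monod_dev$r_max
  fW <- moisture_assim_factor(W, profile$moisture, smooth) *
    moisture_resp_factor(W, profile$moisture, smooth)
  fA <- if (identical(profile$airflow_model, "logistic")) {
    airflow_logistic_rate(A, profile$airflow_logistic) /
      profile$airflow_logistic$k_r_max_A
  } else {
    monod_rate(A, profile$airflow_monod) / profile$airflow_monod$r_max
  }
  r_assim <- assim_stage_factor(T_sum, B, profile$stage, smooth) *
    fT * fFg * fW * fA
  r_mat <- maturity_stage_factor(T_sum, profile$stage, smooth) *
    fT * fFg * fA
  r_dev <- fT * fFd * fW * fA
  if (!is.null(overrides$r_assim)) r_assim <- rep(overrides$r_assim,
                                                  length(times))
  if (!is.null(overrides$r_mat)) r_mat <- rep(overrides$r_mat, length(times))
  if (!is.null(overrides$r_dev)) r_dev <- rep(overrides$r_dev, length(times))
  g <- profile$growth
  phi_ing <- r_assim * g$k_inges * B
  phi_excr <- g$k_alpha_excr * phi_ing
  phi_assim <- g$k_alpha_assim * phi_ing
  phi_eff <- (1 - g$k_alpha_excr - g$k_alpha_assim) * phi_ing
  phi_mat_maint <- r_mat * g$k_maint * B
  data.frame(r_assim = r_assim, r_mat = r_mat, r_dev = r_dev,
             phi_B_ing = phi_ing, phi_B_excr = phi_excr,
             phi_B_assim = phi_assim, phi_B_eff = phi_eff,
             phi_B_mat_maint = phi_mat_maint,
             phi_B_metab = phi_assim + phi_mat_maint)
}

#' Simulate larval growth and development
#'
#' Integrates the dry-mass and development-sum ODEs over a constant
#' environment or a time-varying schedule with an adaptive Runge-Kutta 4(5)
#' solver, using the smoothed regulators (the piecewise forms are exposed
#' through `smooth = FALSE` for diagnostic use). The returned trajectory
#' carries the state, the three regulators and the full flux breakdown on
#' the output grid, plus the detected stage events.
#'
#' @param profile a [parameter_profile()].
#' @param env an [env_state()] (constant conditions) or an
#'   [environment_schedule()].
#' @param t_end_h simulation horizon, hours (> 0).
#' @param initial_B_dry initial dry mass, g; the default 0.002 g corresponds
#'   to the ~8-day-old neonates used to start rearing experiments.
#' @param initial_T_sum initial development sum, h.
#' @param dt_out output grid step, h (ignored when `times` is given).
#' @param times optional explicit output times, h (0 is prepended if absent).
#' @param rtol,atol solver tolerances. The defaults (1e-8, 1e-12 g) are
#'   strict because the regulator products span orders of magnitude near the
#'   stage switches and trajectories can traverse many e-folds of mass.
#' @param method `"ode45"` (Dormand-Prince 4(5), default), or any method name
#'   accepted by [deSolve::ode()] such as `"lsoda"`.
#' @param smooth logical; smoothed switching functions (default).
#' @param interpolation schedule interpolation, `"hold"` or `"linear"`.
#' @param regulators optional constant overrides, see [regulators_at()].
#' @param annotate recompute regulators and fluxes on the output grid
#'   (disable for speed inside iterative fitting).
#' @return An object of class `larva_trajectory`: list with `data` (data
#'   frame `time_h`, `B_dry_g`, `T_sum_h`, `r_assim`, `r_mat`, `r_dev` and
#'   the six `phi_*` fluxes), `events` (see [detect_stage_events()]), and the
#'   simulation settings.
#' @examples
#' prof <- load_profile("table3_recalibrated_D1D5")
#' traj <- simulate_larva(prof, reference_env(prof, B_feed = 0.02), 900)
#' traj$events
#' @export
simulate_larva <- function(profile, env, t_end_h,
                           initial_B_dry = 0.002, initial_T_sum = 0,
                           dt_out = 0.5, times = NULL,
                           rtol = 1e-8, atol = 1e-12,
                           method = "ode45", smooth = TRUE,
                           interpolation = c("hold", "linear"),
                           regulators = NULL, annotate = TRUE) {
  interpolation <- match.arg(interpolation)
  validate_profile(profile)
  schedule <- as_schedule(env)
  .check(.is_num1(t_end_h) && t_end_h > 0, "t_end_h must be > 0")
  .check(.is_num1(initial_B_dry) && initial_B_dry >= 0,
         "initial_B_dry must be >= 0")
  .check(.is_num1(initial_T_sum) && initial_T_sum >= 0,
         "initial_T_sum must be >= 0")
  if (!is.null(regulators)) {
    .check(is.list(regulators) &&
             all(names(regulators) %in% c("r_assim", "r_mat", "r_dev")),
           "regulators overrides must be named r_assim/r_mat/r_dev")
  }
  if (is.null(times)) {
    times <- seq(0, t_end_h, by = dt_out)
    if (times[length(times)] < t_end_h) times <- c(times, t_end_h)
  } else {
    times <- sort(unique(as.numeric(times)))
    if (times[1] > 0) times <- c(0, times)
    .check(all(times >= 0), "output times must be >= 0")
  }

  rhs <- .make_rhs(profile, schedule, smooth, interpolation,
                   regulators %||% list())
  solver_method <- if (identical(method, "ode45")) rkMethod("ode45") else method
  out <- ode(y = c(B = initial_B_dry, T_sum = initial_T_sum),
             times = times, func = rhs, parms = NULL,
             method = solver_method, rtol = rtol, atol = atol)
  out <- unclass(out)
  .check(nrow(out) == length(times) && all(is.finite(out)),
         "integration failed: solver stopped early or produced non-finite ",
         "values (last valid time ", out[nrow(out), 1], " h)")

  B <- pmax(out[, "B"], 0)
  T_sum <- pmax(out[, "T_sum"], 0)
  d <- data.frame(time_h = times, B_dry_g = B, T_sum_h = T_sum)
  if (annotate) {
    d <- cbind(d, .annotate_trajectory(times, B, T_sum, profile, schedule,
                                       smooth, interpolation,
                                       regulators %||% list()))
  }
  traj <- structure(
    list(data = d,
         profile_name = profile$name, smooth = smooth,
         stage = profile$stage, rtol = rtol, atol = atol),
    class = "larva_trajectory")
  traj$events <- detect_stage_events(traj, profile$stage)
  traj
}

#' @export
print.larva_trajectory <- function(x, ...) {
  d <- x$data
  cat("<larva_trajectory> profile:", x$profile_name,
      if (x$smooth) "(smoothed switches)" else "(piecewise switches)", "\n")
  cat(sprintf("  %d points over %.1f h; final B_dry %.4g g, final T_sum %.1f h\n",
              nrow(d), max(d$time_h), d$B_dry_g[nrow(d)],
              d$T_sum_h[nrow(d)]))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("    %-12s t = %8.2f h  (value %.4g)\n",
                  x$events$event[i], x$events$time_h[i], x$events$value[i]))
    }
  }
  invisible(x)
}

#' Detect stage events on a trajectory
#'
#' Finds the times at which the development sum crosses the three stage
#' milestones (by bracketing on the output grid and root-finding on a
#' monotone interpolant, resolving crossings well below 0.01 h), and the time
#' and value of the dry-mass maximum on the output grid.
#'
#' When growth saturates towards the asymptotic mass the trajectory can sit
#' within solver accuracy of its maximum for hundreds of hours, making the
#' literal argmax a coin toss among numerically tied points. Ties within the
#' relative tolerance `peak_tol` therefore resolve to the *latest* attaining
#' time, which identifies the shoulder where the maturation decline begins —
#' the biologically meaningful harvest point.
#'
#' @param traj a `larva_trajectory`.
#' @param stage a [stage_params()]; defaults to the one stored on the
#'   trajectory.
#' @param peak_tol relative tolerance for peak ties (default `1e-6`, about
#'   the integration accuracy).
#' @return Data frame with columns `event` (`k_T_sum_1`, `k_T_sum_2`,
#'   `k_T_sum_3`, `B_dry_peak`), `time_h` and `value` (the milestone, or the
#'   peak mass). Milestones not reached within the simulated span are absent.
#' @export
detect_stage_events <- function(traj, stage = NULL, peak_tol = 1e-6) {
  stage <- stage %||% traj$stage
  d <- traj$data
  tt <- d$time_h
  ts <- d$T_sum_h
  events <- data.frame(event = character(0), time_h = numeric(0),
                       value = numeric(0))
  milestones <- c(k_T_sum_1 = stage$k_T_sum_1, k_T_sum_2 = stage$k_T_sum_2,
                  k_T_sum_3 = stage$k_T_sum_3)
  sf <- NULL
  if (length(tt) >= 2 && all(diff(ts) >= 0) && any(diff(ts) > 0)) {
    sf <- tryCatch(splinefun(tt, ts, method = "hyman"),
                   error = function(e) NULL)
  }
  if (is.null(sf)) sf <- function(x) approx(tt, ts, xout = x)$y
  for (nm in names(milestones)) {
    m <- milestones[[nm]]
    if (ts[1] >= m) {
      events <- rbind(events, data.frame(event = nm, time_h = tt[1],
                                         value = m))
    } else if (max(ts) >= m) {
      idx <- which(ts >= m)[1]
      t_cross <- uniroot(function(x) sf(x) - m, c(tt[idx - 1], tt[idx]),
                         tol = 1e-6)$root
      events <- rbind(events, data.frame(event = nm, time_h = t_cross,
                                         value = m))
    }
  }
  b_max <- max(d$B_dry_g)
  i_peak <- max(which(d$B_dry_g >= b_max - peak_tol * abs(b_max)))
  events <- rbind(events,
                  data.frame(event = "B_dry_peak", time_h = tt[i_peak],
                             value = d$B_dry_g[i_peak]))
  rownames(events) <- NULL
  events
}

#' Write a trajectory (and its events) to CSV
#'
#' @param traj a `larva_trajectory`.
#' @param path output CSV for the state/regulator/flux table.
#' @param events_path optional CSV for the event table.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, events_path = NULL) {
  .write_csv17(traj$data, path)
  if (!is.null(events_path)) .write_csv17(traj$events, events_path)
  invisible(path)
}
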