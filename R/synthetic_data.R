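# Seeded synthetic-data generators emulating the structure of the literature
# dataset classes used for calibration: single-factor response sweeps
# (temperature, feed density, moisture, airflow) and dry-mass-over-time
# trajectories under different feeding rates. All generators are
# deterministic given their seed and record the generating truth for
# parameter-recovery testing.

#' Observation-noise specification
#'
#' @param kind `"gaussian"`, `"lognormal"` or `"none"`. Gaussian noise has
#'   standard deviation `scale * max(clean response)` (a fraction-of-maximum
#'   model, matching the normalized fitting workflow); lognormal noise
#'   multiplies by `exp(N(0, scale))`.
#' @param scale noise scale, >= 0. Default 0.05 (5 % of the response
#'   maximum, a typical replicate spread for insect growth assays).
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "lognormal", "none"),
                       scale = 0.05, seed = 1) {
  kind <- match.arg(kind)
  .check(.is_num1(scale) && scale >= 0, "noise scale must be >= 0")
  .check(.is_num1(seed), "seed must be a single number")
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "noise_spec")
}

.apply_noise <- function(clean, noise) {
  if (noise$kind == "none" || noise$scale == 0) return(clean)
  .with_seed(noise$seed, {
    noisy <- switch(noise$kind,
      gaussian = clean + rnorm(length(clean), 0,
                               noise$scale * max(abs(clean), 1e-300)),
      lognormal = clean * exp(rnorm(length(clean), 0, noise$scale)))
    pmax(noisy, 0)  # responses are physically nonnegative
  })
}

# Default factor grids mirroring the ranges covered by the literature
# sweeps: temperature 10-42 degC, feed 0-0.2 g/d per larva, moisture
# 0.1-0.95 kg/kg, airflow 0-3 l/min. Temperature and moisture sweeps are
# uniform (as in the source experiments); feed and airflow sweeps are
# geometric series plus a zero point, the standard design for saturating
# dose-response curves whose half-saturation sits decades below the range
# maximum (feeding-rate experiments use multiplicative ration series).
.geom_grid <- function(xmax, n, span = 200) {
  c(0, exp(seq(log(xmax / span), log(xmax), length.out = n - 1)))
}

.default_grid <- function(model, n) {
  switch(model,
    arrhenius = ,
    logan10 = seq(10, 42, length.out = n),
    monod_dev = ,
    monod_grw = .geom_grid(0.2, n),
    moisture = seq(0.1, 0.95, length.out = n),
    airflow_monod = ,
    airflow_logistic = .geom_grid(3, n),
    stop("unknown model id: ", model, call. = FALSE))
}

.profile_static_params <- function(profile, model) {
  info <- .static_model_info(model)
  p <- info$defaults
  map <- list(
    arrhenius = c("k_r_ref_T", "k_T_A", "k_T_AL", "k_T_AH", "k_T_ref",
                  "k_T_L", "k_T_H"),
    logan10 = c("k_r_max_T", "k_r_base_T", "k_rho_T", "k_T_base",
                "k_T_max", "k_delta_T"),
    monod_dev = c("k_r_max_dm", "k_B_half_dm"),
    monod_grw = c("k_r_max_gm", "k_B_half_gm"),
    moisture = c("k_r_max_W", "k_W_med_C1", "k_W_med_C2", "k_W_med_C3",
                 "k_W_med_crit"),
    airflow_monod = c("k_r_max_A", "k_A_half"))
  if (model == "airflow_logistic") {
    al <- profile$airflow_logistic
    .check(!is.null(al), "profile has no airflow_logistic parameters")
    p["k_r_max_A"] <- al$k_r_max_A
    p["k_A_inf"] <- al$k_A_inf
    p["k_A_trans"] <- al$k_A_trans
  } else {
    for (s in map[[model]]) p[s] <- profile_get(profile, s)
  }
  p
}

#' Generate a synthetic single-factor response dataset
#'
#' Evaluates the chosen static model with the profile's parameters on a
#' factor grid and adds observation noise, truncated at zero. The generating
#' parameter vector is attached as attribute `true_params` for
#' parameter-recovery tests.
#'
#' @param model a model id from [static_model_ids()].
#' @param profile generating [parameter_profile()].
#' @param n number of grid points (ignored when `grid` is given).
#' @param grid optional explicit factor grid.
#' @param noise a [noise_spec()]; its `seed` is combined with `seed`.
#' @param seed integer seed for this dataset.
#' @param id dataset label.
#' @return A [rate_dataset()] with attributes `true_params` (full generating
#'   parameter vector) and `clean` (noise-free responses).
#' @export
generate_response_dataset <- function(model,
                                      profile = load_profile(),
                                      n = 30, grid = NULL,
                                      noise = noise_spec(), seed = 1,
                                      id = model) {
  .check(model %in% static_model_ids(), "unknown model id: ", model)
  validate_profile(profile)
  grid <- grid %||% .default_grid(model, n)
  truth <- .profile_static_params(profile, model)
  info <- .static_model_info(model)
  clean <- info$fun(truth, grid)
  noise$seed <- noise$seed + as.integer(seed) * 1000L
  resp <- .apply_noise(clean, noise)
  ds <- rate_dataset(grid, resp, info$factor_kind, id = id)
  attr(ds, "true_params") <- truth
  attr(ds, "clean") <- clean
  ds
}

#' Generate a synthetic dry-mass trajectory dataset
#'
#' Simulates the dynamic model under the given environment, samples the dry
#' mass at the requested times and adds observation noise. Returns both the
#' noisy observations (the shape of the dry-mass-over-time validation
#' datasets) and the clean simulated trajectory.
#'
#' @param profile generating [parameter_profile()].
#' @param env an [env_state()] or [environment_schedule()].
#' @param times observation times, h.
#' @param initial_B_dry initial dry mass, g (default 2 mg, the starting
#'   weight of ~8-day-old larvae in rearing experiments).
#' @param noise a [noise_spec()]; scale is relative to the trajectory
#'   maximum.
#' @param seed integer seed.
#' @param id dataset label.
#' @return List with `observations` (data frame `time_h`, `B_dry_g`,
#'   `source_id`) and `trajectory` (the clean `larva_trajectory`).
#' @export
generate_trajectory_dataset <- function(profile, env,
                                        times = seq(0, 600, by = 12),
                                        initial_B_dry = 0.002,
                                        noise = noise_spec(), seed = 1,
                                        id = "traj") {
  validate_profile(profile)
  traj <- simulate_larva(profile, env, t_end_h = max(times),
                         times = times, initial_B_dry = initial_B_dry)
  clean <- traj$data$B_dry_g[match(round(times, 9),
                                   round(traj$data$time_h, 9))]
  noise$seed <- noise$seed + as.integer(seed) * 1000L
  obs <- .apply_noise(clean, noise)
  list(observations = data.frame(time_h = times, B_dry_g = obs,
                                 source_id = id),
       trajectory = traj)
}

#' Write a suite of synthetic CSV fixtures
#'
#' Writes one fixture per dataset class used in the calibration workflow:
#' four temperature sweeps (`T1`-`T4`, different noise draws emulating
#' different feed types), feed-density development and growth sweeps
#' (`F1_dev`, `F1_grw`), a moisture sweep (`M1`), an airflow sweep (`A1`), a
#' reference trajectory (`G1`) and five trajectories under increasing
#' feeding rates (`D1`-`D5`). All files are synthetic, generated from the
#' shipped parameter profiles; regeneration with the same seed is
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @param profile generating profile for the response sweeps.
#' @return Invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(dir, seed = 1,
                               profile = load_profile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  files <- character(0)
  put <- function(name, df) {
    path <- file.path(dir, paste0(name, ".csv"))
    .write_csv17(df, path)
    files <<- c(files, path)
  }
  for (i in 1:4) {
    ds <- generate_response_dataset("logan10", profile,
                                    noise = noise_spec(seed = seed),
                                    seed = seed + i, id = paste0("T", i))
    put(paste0("T", i), as.data.frame(ds))
  }
  f_dev <- generate_response_dataset("monod_dev", profile,
                                     noise = noise_spec(seed = seed),
                                     seed = seed + 10, id = "F1_dev")
  put("F1_dev", as.data.frame(f_dev))
  f_grw <- generate_response_dataset("monod_grw", profile,
                                     noise = noise_spec(seed = seed),
                                     seed = seed + 11, id = "F1_grw")
  put("F1_grw", as.data.frame(f_grw))
  m1 <- generate_response_dataset("moisture", profile,
                                  noise = noise_spec(seed = seed),
                                  seed = seed + 12, id = "M1")
  put("M1", as.data.frame(m1))
  a1 <- generate_response_dataset("airflow_monod", profile,
                                  noise = noise_spec(seed = seed),
                                  seed = seed + 13, id = "A1")
  put("A1", as.data.frame(a1))
  prof_d <- load_profile("table3_recalibrated_D1D5")
  feeds <- c(G1 = 0.05, D1 = 0.01, D2 = 0.025, D3 = 0.05, D4 = 0.1,
             D5 = 0.2)
  for (i in seq_along(feeds)) {
    nm <- names(feeds)[i]
    td <- generate_trajectory_dataset(
      prof_d, reference_env(prof_d, B_feed = feeds[[i]]),
      times = seq(0, 700, by = 12),
      noise = noise_spec(seed = seed), seed = seed + 20 + i, id = nm)
    put(nm, td$observations)
  }
  invisible(files)
}

#' @export
as.data.frame.rate_dataset <- function(x, ...) {
  data.frame(factor = x$factor, response = x$response,
             source_id = x$source_id, unit_factor = x$unit_factor,
             unit_response = x$unit_response)
}
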