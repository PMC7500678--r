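# Parameter estimation: dataset preparation (rate conversion, normalization,
# grouping), multi-start bounded nonlinear least squares for the static rate
# models and for the dynamic model, subset recalibration, goodness of fit.

#' Rate/response dataset
#'
#' Observations of a response (development or growth rate, development time,
#' or dry mass) against one varied environmental factor, the unit handled by
#' the estimation workflow.
#'
#' @param factor numeric vector of factor values (temperature, feed density,
#'   moisture, airflow or time).
#' @param response numeric vector of responses, same length, nonnegative.
#' @param factor_kind one of `"temperature"`, `"feed_density"`,
#'   `"moisture"`, `"airflow"`, `"time"`.
#' @param id dataset label (e.g. `"T1"`).
#' @param source_id per-point source labels (defaults to `id`).
#' @param unit_factor,unit_response unit strings; sensible defaults per
#'   factor kind.
#' @param normalized logical: have responses been scaled to max 1?
#' @return An object of class `rate_dataset`.
#' @export
rate_dataset <- function(factor, response,
                         factor_kind = c("temperature", "feed_density",
                                         "moisture", "airflow", "time"),
                         id = "ds", source_id = NULL,
                         unit_factor = NULL, unit_response = NULL,
                         normalized = FALSE) {
  factor_kind <- match.arg(factor_kind)
  .check(is.numeric(factor) && is.numeric(response) &&
           length(factor) == length(response) && length(factor) > 0,
         "rate_dataset: factor and response must be equal-length nonempty ",
         "numeric vectors")
  .check(all(is.finite(factor)) && all(is.finite(response)),
         "rate_dataset: values must be finite")
  .check(all(response >= 0), "rate_dataset: responses must be >= 0")
  default_units <- c(temperature = "degC", feed_density = "g d-1",
                     moisture = "kg kg-1", airflow = "l min-1", time = "h")
  structure(
    list(id = as.character(id), factor_kind = factor_kind,
         factor = as.numeric(factor), response = as.numeric(response),
         source_id = as.character(source_id %||% rep(id, length(factor))),
         unit_factor = unit_factor %||% unname(default_units[factor_kind]),
         unit_response = unit_response %||%
           if (normalized) "normalized" else "response",
         normalized = isTRUE(normalized)),
    class = "rate_dataset")
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat(sprintf("<rate_dataset> %s: %d points, %s [%s] -> response [%s]%s\n",
              x$id, length(x$factor), x$factor_kind, x$unit_factor,
              x$unit_response, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Convert development times to rates
#'
#' Development-time observations (days to reach a stage) are converted to
#' development rates by elementwise reciprocal before rate-model fitting.
#'
#' @param times development times, all strictly positive.
#' @return `1 / times`, the development rates in reciprocal units.
#' @export
development_time_to_rate <- function(times) {
  .check(is.numeric(times) && all(is.finite(times)),
         "times must be finite numeric")
  .check(all(times > 0), "development times must be > 0")
  1 / times
}

#' Normalize a dataset to its observed maximum
#'
#' Divides the responses by their observed maximum so that datasets measured
#' on different feeds or scales become comparable (maximum exactly 1). The
#' scaling factor is kept as attribute `norm_max` so fitted maximum-rate
#' parameters can later be mapped back with [rescale_to_observed()].
#'
#' @param ds a [rate_dataset()].
#' @return The normalized [rate_dataset()].
#' @export
normalize_dataset <- function(ds) {
  .check(inherits(ds, "rate_dataset"), "ds must be a rate_dataset")
  mx <- max(ds$response)
  .check(mx > 0, "cannot normalize: all responses are zero")
  out <- rate_dataset(ds$factor, ds$response / mx, ds$factor_kind, ds$id,
                      ds$source_id, ds$unit_factor, "normalized",
                      normalized = TRUE)
  attr(out, "norm_max") <- mx
  attr(out, "true_params") <- attr(ds, "true_params")
  out
}

#' Pool datasets measuring the same factor
#'
#' Combines datasets that vary the same factor into one, either by pooling
#' all observations (default; each point keeps its source label) or, when
#' every dataset shares an identical factor grid, by pointwise averaging of
#' the responses.
#'
#' @param dss nonempty list of [rate_dataset()]s with a common factor kind
#'   and unit.
#' @param method `"pool"` or `"average"`.
#' @param id label for the pooled dataset.
#' @return A [rate_dataset()].
#' @export
group_datasets <- function(dss, method = c("pool", "average"), id = NULL) {
  method <- match.arg(method)
  .check(is.list(dss) && length(dss) > 0, "dss must be a nonempty list")
  for (d in dss) .check(inherits(d, "rate_dataset"),
                        "all elements must be rate_datasets")
  kinds <- unique(vapply(dss, `[[`, character(1), "factor_kind"))
  .check(length(kinds) == 1, "cannot group datasets with mixed factor ",
         "kinds: ", paste(kinds, collapse = ", "))
  units <- unique(vapply(dss, `[[`, character(1), "unit_factor"))
  .check(length(units) == 1, "cannot group datasets with mixed factor ",
         "units: ", paste(units, collapse = ", "))
  id <- id %||% paste(vapply(dss, `[[`, character(1), "id"),
                      collapse = "+")
  if (method == "average") {
    grids <- lapply(dss, `[[`, "factor")
    same <- all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                       logical(1)))
    .check(same, "method 'average' requires identical factor grids")
    resp <- rowMeans(do.call(cbind, lapply(dss, `[[`, "response")))
    return(rate_dataset(grids[[1]], resp, kinds, id,
                        normalized = all(vapply(dss, `[[`, logical(1),
                                                "normalized"))))
  }
  rate_dataset(
    factor = unlist(lapply(dss, `[[`, "factor")),
    response = unlist(lapply(dss, `[[`, "response")),
    factor_kind = kinds, id = id,
    source_id = unlist(lapply(dss, `[[`, "source_id")),
    unit_factor = units,
    normalized = all(vapply(dss, `[[`, logical(1), "normalized")))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the observed
#' mean; can be negative for fits worse than the mean.
#'
#' @param observed,predicted equal-length numeric vectors, `length >= 2`,
#'   with nonzero variance in `observed`.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  .check(is.numeric(observed) && is.numeric(predicted) &&
           length(observed) == length(predicted) && length(observed) >= 2,
         "observed and predicted must be equal-length (>= 2) numeric")
  ss_tot <- sum((observed - mean(observed))^2)
  .check(ss_tot > 0, "observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

# --- static model registry --------------------------------------------------

# Raw model functions: full named parameter vector -> response. No input
# validation (they sit inside optimizer loops); invalid parameter orderings
# must still evaluate finitely so that bad candidates are rejected by
# residual value.
.arrhenius_fun <- function(p, x) {
  TK <- x + 273.15
  num <- .exp_clamped(p[["k_T_A"]] / p[["k_T_ref"]] - p[["k_T_A"]] / TK)
  den <- 1 +
    .exp_clamped(p[["k_T_AL"]] / TK - p[["k_T_AL"]] / p[["k_T_L"]]) +
    .exp_clamped(p[["k_T_AH"]] / p[["k_T_H"]] - p[["k_T_AH"]] / TK)
  p[["k_r_ref_T"]] * num / den
}

.logan10_fun <- function(p, x) {
  kg <- (p[["k_r_max_T"]] - p[["k_r_base_T"]]) / max(p[["k_r_base_T"]], 1e-12)
  den <- 1 + kg * .exp_clamped(-p[["k_rho_T"]] * (x - p[["k_T_base"]])) +
    .exp_clamped(-(p[["k_T_max"]] - x) / max(p[["k_delta_T"]], 1e-9))
  p[["k_r_max_T"]] / den
}

.monod_fun <- function(rmax_name, khalf_name) {
  function(p, x) p[[rmax_name]] * x / (x + max(p[[khalf_name]], 1e-12))
}

.moisture_fun <- function(p, x) {
  a <- (x - p[["k_W_med_C1"]]) /
    max(p[["k_W_med_C2"]] - p[["k_W_med_C1"]], 1e-9)
  r <- (x - p[["k_W_med_crit"]]) /
    min(p[["k_W_med_C3"]] - p[["k_W_med_crit"]], -1e-9)
  p[["k_r_max_W"]] * pmin(pmax(a, 0), 1) * pmin(pmax(r, 0), 1)
}

.airflow_logistic_fun <- function(p, x) {
  p[["k_r_max_A"]] /
    (1 + .exp_clamped((x - p[["k_A_inf"]]) / p[["k_A_trans"]]))
}

#' Available static model identifiers
#'
#' Model ids accepted by [fit_static()] and
#' [generate_response_dataset()].
#'
#' @return Character vector of model ids.
#' @export
static_model_ids <- function() {
  c("arrhenius", "logan10", "monod_dev", "monod_grw", "moisture",
    "airflow_monod", "airflow_logistic")
}

# Per-model metadata: defaults (shipped estimates), default free set, bounds
# (partly data-adaptive), model function, names of rate-scale parameters
# (the ones multiplied by the observed maximum when un-normalizing), and the
# factor kind the model expects.
.static_model_info <- function(model, ds = NULL) {
  mx <- if (is.null(ds)) 1 else max(ds$response)
  xmax <- if (is.null(ds)) 1 else max(ds$factor)
  prof <- .builtin_profile("table3_original")
  switch(
    model,
    arrhenius = list(
      defaults = c(k_r_ref_T = prof$arrhenius$k_r_ref_T,
                   k_T_A = prof$arrhenius$k_T_A,
                   k_T_AL = prof$arrhenius$k_T_AL,
                   k_T_AH = prof$arrhenius$k_T_AH,
                   k_T_ref = prof$arrhenius$k_T_ref,
                   k_T_L = prof$arrhenius$k_T_L,
                   k_T_H = prof$arrhenius$k_T_H),
      # boundary Arrhenius temperatures and the reference/boundary
      # temperatures are weakly identifiable from single sweeps and are
      # fixed by default (see the methods vignette); free on request.
      free_default = c("k_r_ref_T", "k_T_A"),
      lower = c(k_r_ref_T = 1e-4, k_T_A = 1000, k_T_AL = 1e4,
                k_T_AH = 1e4, k_T_ref = 273.15, k_T_L = 263.15,
                k_T_H = 273.15),
      upper = c(k_r_ref_T = 10 * max(mx, 1e-6), k_T_A = 30000,
                k_T_AL = 2e5, k_T_AH = 2e5, k_T_ref = 323.15,
                k_T_L = 313.15, k_T_H = 333.15),
      fun = .arrhenius_fun, rate_scale = "k_r_ref_T",
      factor_kind = "temperature"),
    logan10 = list(
      defaults = c(k_r_max_T = prof$logan10$k_r_max_T,
                   k_r_base_T = prof$logan10$k_r_base_T,
                   k_rho_T = prof$logan10$k_rho_T,
                   k_T_base = prof$logan10$k_T_base,
                   k_T_max = prof$logan10$k_T_max,
                   k_delta_T = prof$logan10$k_delta_T),
      # k_T_base and k_r_base_T enter the response only through the
      # combination k_gamma * exp(k_rho_T * k_T_base): fitting both is
      # structurally rank-deficient, so the threshold temperature is a
      # fixed anchor by default (free on request).
      free_default = c("k_r_max_T", "k_r_base_T", "k_rho_T",
                       "k_T_max", "k_delta_T"),
      lower = c(k_r_max_T = 0.05 * max(mx, 1e-6), k_r_base_T = 1e-4,
                k_rho_T = 0.02, k_T_base = 0, k_T_max = 30,
                k_delta_T = 0.2),
      upper = c(k_r_max_T = 5 * max(mx, 1e-6),
                k_r_base_T = 2 * max(mx, 1e-6), k_rho_T = 2,
                k_T_base = 30, k_T_max = 60, k_delta_T = 20),
      fun = .logan10_fun, rate_scale = c("k_r_max_T", "k_r_base_T"),
      factor_kind = "temperature"),
    monod_dev = list(
      defaults = c(k_r_max_dm = prof$monod_dev$r_max,
                   k_B_half_dm = prof$monod_dev$k_half),
      free_default = c("k_r_max_dm", "k_B_half_dm"),
      lower = c(k_r_max_dm = 1e-4, k_B_half_dm = 1e-5 * max(xmax, 1e-6)),
      upper = c(k_r_max_dm = 10 * max(mx, 1e-6),
                k_B_half_dm = 10 * max(xmax, 1e-6)),
      fun = .monod_fun("k_r_max_dm", "k_B_half_dm"),
      rate_scale = "k_r_max_dm", factor_kind = "feed_density"),
    monod_grw = list(
      defaults = c(k_r_max_gm = prof$monod_grw$r_max,
                   k_B_half_gm = prof$monod_grw$k_half),
      free_default = c("k_r_max_gm", "k_B_half_gm"),
      lower = c(k_r_max_gm = 1e-4, k_B_half_gm = 1e-5 * max(xmax, 1e-6)),
      upper = c(k_r_max_gm = 10 * max(mx, 1e-6),
                k_B_half_gm = 10 * max(xmax, 1e-6)),
      fun = .monod_fun("k_r_max_gm", "k_B_half_gm"),
      rate_scale = "k_r_max_gm", factor_kind = "feed_density"),
    moisture = list(
      defaults = c(k_r_max_W = prof$moisture$k_r_max_W,
                   k_W_med_C1 = prof$moisture$k_W_med_C1,
                   k_W_med_C2 = prof$moisture$k_W_med_C2,
                   k_W_med_C3 = prof$moisture$k_W_med_C3,
                   k_W_med_crit = prof$moisture$k_W_med_crit),
      free_default = c("k_r_max_W", "k_W_med_C1", "k_W_med_C2",
                       "k_W_med_C3", "k_W_med_crit"),
      lower = c(k_r_max_W = 0.05 * max(mx, 1e-6), k_W_med_C1 = 0,
                k_W_med_C2 = 0.3, k_W_med_C3 = 0.55, k_W_med_crit = 0.78),
      upper = c(k_r_max_W = 5 * max(mx, 1e-6), k_W_med_C1 = 0.6,
                k_W_med_C2 = 0.78, k_W_med_C3 = 0.82, k_W_med_crit = 1),
      fun = .moisture_fun, rate_scale = "k_r_max_W",
      factor_kind = "moisture"),
    airflow_monod = list(
      defaults = c(k_r_max_A = prof$airflow_monod$r_max,
                   k_A_half = prof$airflow_monod$k_half),
      free_default = c("k_r_max_A", "k_A_half"),
      lower = c(k_r_max_A = 1e-4, k_A_half = 1e-5 * max(xmax, 1e-6)),
      upper = c(k_r_max_A = 10 * max(mx, 1e-6),
                k_A_half = 10 * max(xmax, 1e-6)),
      fun = .monod_fun("k_r_max_A", "k_A_half"),
      rate_scale = "k_r_max_A", factor_kind = "airflow"),
    airflow_logistic = list(
      defaults = c(k_r_max_A = max(mx, 1e-6), k_A_inf = 0.5 * xmax,
                   k_A_trans = -0.3),
      free_default = c("k_r_max_A", "k_A_inf", "k_A_trans"),
      lower = c(k_r_max_A = 1e-4, k_A_inf = 0, k_A_trans = -10),
      upper = c(k_r_max_A = 10 * max(mx, 1e-6), k_A_inf = max(xmax, 1e-6),
                k_A_trans = -1e-3),
      fun = .airflow_logistic_fun, rate_scale = "k_r_max_A",
      factor_kind = "airflow"),
    stop("unknown static model id: ", model, call. = FALSE))
}

# Stratified multi-start matrix: first row is the supplied centre start,
# remaining rows a seeded Latin-hypercube sample of the box. Positive
# parameters spanning decades are sampled on a log scale.
.make_starts <- function(centre, lower, upper, n_starts, seed) {
  d <- length(centre)
  centre <- pmin(pmax(centre, lower), upper)
  starts <- matrix(centre, nrow = 1)
  if (n_starts > 1) {
    u <- .with_seed(seed, .lhs_unit(n_starts - 1, d))
    logscale <- lower > 0 & upper / pmax(lower, 1e-300) > 100
    sc <- matrix(0, n_starts - 1, d)
    for (j in seq_len(d)) {
      sc[, j] <- if (logscale[j]) {
        exp(log(lower[j]) + u[, j] * (log(upper[j]) - log(lower[j])))
      } else {
        lower[j] + u[, j] * (upper[j] - lower[j])
      }
    }
    starts <- rbind(starts, sc)
  }
  colnames(starts) <- names(centre)
  starts
}

.run_multistart <- function(starts, lower, upper, resid_fn, maxiter = 300) {
  n_starts <- nrow(starts)
  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    results[[s]] <- tryCatch({
      fit <- nls.lm(par = starts[s, ], lower = lower, upper = upper,
                    fn = resid_fn,
                    control = nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-14, ptol = 1e-14))
      list(par = fit$par, rss = fit$deviance,
           converged = fit$info %in% 1:4, message = fit$message)
    }, error = function(e) {
      list(par = starts[s, ], rss = Inf, converged = FALSE,
           message = conditionMessage(e))
    })
  }
  results
}

.pick_best <- function(results) {
  rss <- vapply(results, `[[`, numeric(1), "rss")
  conv <- vapply(results, `[[`, logical(1), "converged")
  .check(any(conv & is.finite(rss)),
         "no start converged; diagnostics: ",
         paste(unique(vapply(results, `[[`, character(1), "message")),
               collapse = " | "))
  rss[!conv] <- Inf
  which.min(rss)
}

#' Fit a static rate model by multi-start least squares
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) from a stratified
#' set of starting points: the first start is the shipped default parameter
#' set, the rest a seeded Latin-hypercube sample of the bound box. The best
#' converged start by residual sum of squares wins; results are
#' deterministic given `seed`.
#'
#' Two thermal-model parameters are anchored rather than fitted by default,
#' for identifiability. Arrhenius: only the reference rate and the reference
#' Arrhenius temperature are free — the boundary-correction parameters shift
#' the response by a fraction of the observation noise over realistic sweeps
#' and the reference temperature is redundant with the reference rate.
#' Logan-10: the lower threshold `k_T_base` is fixed, because it enters the
#' response only through the combination
#' `k_gamma * exp(k_rho_T * k_T_base)` and fitting it jointly with
#' `k_r_base_T` is structurally rank-deficient. Pass `free` explicitly to
#' fit any parameter anyway.
#'
#' @param ds a [rate_dataset()].
#' @param model a model id from [static_model_ids()].
#' @param free character vector of parameters to estimate (default: the
#'   model's standard free set); the rest stay at their defaults.
#' @param bounds optional named list of `c(lower, upper)` overrides.
#' @param start optional named numeric vector overriding the centre start.
#' @param n_starts number of starting points (>= 1).
#' @param seed integer seed for the start sample.
#' @return An object of class `fit_result`: estimated parameters (`par`),
#'   fixed parameters, bounds, `rss`, `r_squared`, per-start convergence
#'   table, and the index of the winning start.
#' @export
fit_static <- function(ds, model, free = NULL, bounds = NULL, start = NULL,
                       n_starts = 32, seed = 1) {
  .check(inherits(ds, "rate_dataset"), "ds must be a rate_dataset")
  .check(length(ds$factor) >= 2, "need at least two observations")
  .check(length(unique(ds$factor)) >= 2,
         "factor has zero variance: design is non-identifiable")
  .check(.is_num1(n_starts) && n_starts >= 1, "n_starts must be >= 1")
  info <- .static_model_info(model, ds)
  free <- free %||% info$free_default
  .check(all(free %in% names(info$defaults)),
         "unknown parameter(s) in free: ",
         paste(setdiff(free, names(info$defaults)), collapse = ", "))
  .check(length(free) >= 1, "free must select at least one parameter")
  lower <- info$lower[free]
  upper <- info$upper[free]
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      .check(nm %in% free, "bounds given for non-free parameter: ", nm)
      lower[nm] <- bounds[[nm]][1]
      upper[nm] <- bounds[[nm]][2]
    }
  }
  .check(all(is.finite(lower)) && all(is.finite(upper)) &&
           all(lower < upper), "bounds must be finite with lower < upper")
  centre <- info$defaults[free]
  if (!is.null(start)) centre[names(start)] <- start
  pars_full <- info$defaults
  resid_fn <- function(p) {
    pars_full[free] <- p
    info$fun(pars_full, ds$factor) - ds$response
  }
  starts <- .make_starts(centre, lower, upper, n_starts, seed)
  results <- .run_multistart(starts, lower, upper, resid_fn)
  best <- .pick_best(results)
  par <- results[[best]]$par
  pars_full[free] <- par
  pred <- info$fun(pars_full, ds$factor)
  structure(
    list(model = model, par = setNames(as.numeric(par), free),
         fixed = info$defaults[setdiff(names(info$defaults), free)],
         lower = lower, upper = upper,
         rss = results[[best]]$rss,
         r_squared = r_squared(ds$response, pred),
         n_starts = n_starts, best_start = best,
         convergence = data.frame(
           start = seq_len(nrow(starts)),
           converged = vapply(results, `[[`, logical(1), "converged"),
           rss = vapply(results, `[[`, numeric(1), "rss")),
         n_obs = length(ds$factor), dataset_id = ds$id,
         normalized = ds$normalized, seed = seed),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s on %s (%d points)\n", x$model,
              x$dataset_id %||% "data", x$n_obs))
  cat(sprintf("  RSS %.4g | R^2 %.4f | best start %d of %d (%d converged)\n",
              x$rss, x$r_squared, x$best_start, x$n_starts,
              sum(x$convergence$converged)))
  print(signif(x$par, 6))
  invisible(x)
}

#' Map a normalized fit back to the observed scale
#'
#' After fitting on normalized data (maximum response 1), multiplies the
#' fitted maximum-rate parameters by the observed maximum rate; shape
#' parameters (half-saturations, temperatures, widths) are unchanged.
#'
#' @param result a `fit_result` from [fit_static()].
#' @param max_rate the maximum rate observed in the original data (the
#'   `norm_max` attribute set by [normalize_dataset()]).
#' @return The rescaled `fit_result` (flagged with `rescaled = TRUE`).
#' @export
rescale_to_observed <- function(result, max_rate) {
  .check(inherits(result, "fit_result"), "result must be a fit_result")
  .check(.is_num1(max_rate) && max_rate > 0, "max_rate must be > 0")
  info <- .static_model_info(result$model)
  for (nm in info$rate_scale) {
    if (nm %in% names(result$par)) result$par[nm] <- result$par[nm] * max_rate
    if (nm %in% names(result$fixed)) {
      result$fixed[nm] <- result$fixed[nm] * max_rate
    }
  }
  result$rescaled <- TRUE
  result$rescale_factor <- max_rate
  result
}

# --- dynamic model fitting --------------------------------------------------

.as_traj_list <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  .check(is.list(x) && length(x) >= 1, "trajectories must be a nonempty ",
         "list of data frames")
  lapply(x, function(d) {
    .check(is.data.frame(d) && all(c("time_h", "B_dry_g") %in% names(d)),
           "each trajectory needs columns time_h and B_dry_g")
    .check(nrow(d) >= 4, "each trajectory needs at least 4 time points")
    d[order(d$time_h), c("time_h", "B_dry_g")]
  })
}

.dynamic_default_bounds <- function(profile, mask, spread = 5) {
  setNames(lapply(mask, function(s) {
    v <- profile_get(profile, s)
    .check(.is_num1(v) && v > 0, "no finite positive default for ", s,
           "; supply bounds explicitly")
    c(v / spread, v * spread)
  }), mask)
}

#' Fit dynamic-model parameters to dry-mass trajectories
#'
#' Joint bounded least squares of simulated versus observed dry mass across
#' one or more trajectories, each with its own (constant or scheduled)
#' environment. Candidate parameter vectors are written into the profile by
#' symbol ([profile_set()], unvalidated so that out-of-order candidates are
#' rejected by residual value), the model is simulated with
#' [simulate_larva()] at the observation times, and the pooled residuals are
#' minimised by multi-start Levenberg-Marquardt. Only dry mass enters the
#' objective; the development sum is latent. Starts that fail to integrate
#' are marked failed and the remaining starts continue.
#'
#' @param trajectories a data frame (or list of them) with columns `time_h`,
#'   `B_dry_g`.
#' @param envs an [env_state()]/[environment_schedule()] or list of them,
#'   one per trajectory (a single one is recycled).
#' @param profile the starting [parameter_profile()].
#' @param mask character vector of parameter symbols to estimate (see
#'   [profile_symbols()]); at least one.
#' @param bounds optional named list of `c(lower, upper)`; defaults to the
#'   current value divided/multiplied by 5.
#' @param n_starts number of starting points; the first is the current
#'   profile value.
#' @param seed integer seed.
#' @param initial_B_dry optional numeric vector of initial masses, one per
#'   trajectory; defaults to each trajectory's earliest observation.
#' @param solver list of [simulate_larva()] solver options used inside the
#'   objective (default `lsoda`, rtol `1e-8`).
#' @param smooth use smoothed regulators in the simulations (default).
#' @return A `fit_result` with parameters named by symbol, plus the fitted
#'   per-trajectory predictions in `$predictions`.
#' @export
fit_dynamic <- function(trajectories, envs, profile, mask, bounds = NULL,
                        n_starts = 8, seed = 1, initial_B_dry = NULL,
                        solver = list(method = "lsoda", rtol = 1e-8,
                                      atol = 1e-12),
                        smooth = TRUE) {
  trajs <- .as_traj_list(trajectories)
  if (inherits(envs, c("env_state", "environment_schedule"))) {
    envs <- list(envs)
  }
  if (length(envs) == 1 && length(trajs) > 1) {
    envs <- rep(envs, length(trajs))
  }
  .check(length(envs) == length(trajs),
         "need one environment per trajectory")
  .check(is.character(mask) && length(mask) >= 1,
         "mask must name at least one parameter symbol")
  for (s in mask) .symbol_path(s)  # errors on unknown symbols
  validate_profile(profile)
  b <- .dynamic_default_bounds(profile, mask)
  if (!is.null(bounds)) for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]
  lower <- vapply(b[mask], `[`, numeric(1), 1)
  upper <- vapply(b[mask], `[`, numeric(1), 2)
  names(lower) <- names(upper) <- mask
  .check(all(lower < upper), "bounds must satisfy lower < upper")
  init <- initial_B_dry %||%
    vapply(trajs, function(d) d$B_dry_g[1], numeric(1))
  .check(length(init) == length(trajs) && all(init >= 0),
         "initial_B_dry must be one nonnegative value per trajectory")
  obs <- unlist(lapply(trajs, `[[`, "B_dry_g"))
  n_obs <- length(obs)

  resid_fn <- function(p) {
    prof_c <- profile_set(profile, setNames(as.list(p), mask),
                          validate = FALSE)
    pred <- tryCatch(
      unlist(lapply(seq_along(trajs), function(i) {
        tt <- trajs[[i]]$time_h
        sim <- simulate_larva(
          prof_c, envs[[i]], t_end_h = max(tt, 1e-6),
          initial_B_dry = init[i], times = tt,
          rtol = solver$rtol %||% 1e-8, atol = solver$atol %||% 1e-12,
          method = solver$method %||% "lsoda", smooth = smooth,
          annotate = FALSE)
        sim$data$B_dry_g[match(round(tt, 9), round(sim$data$time_h, 9))]
      })),
      error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(rep(1e6, n_obs))
    pred - obs
  }

  centre <- vapply(mask, function(s) profile_get(profile, s), numeric(1))
  starts <- .make_starts(centre, lower, upper, n_starts, seed)
  results <- .run_multistart(starts, lower, upper, resid_fn, maxiter = 200)
  # starts stuck at the failure plateau are failures, not fits
  for (i in seq_along(results)) {
    if (results[[i]]$rss >= 1e10) results[[i]]$converged <- FALSE
  }
  best <- .pick_best(results)
  par <- setNames(as.numeric(results[[best]]$par), mask)
  prof_best <- profile_set(profile, as.list(par), validate = FALSE)
  preds <- lapply(seq_along(trajs), function(i) {
    tt <- trajs[[i]]$time_h
    sim <- simulate_larva(prof_best, envs[[i]], t_end_h = max(tt, 1e-6),
                          initial_B_dry = init[i], times = tt,
                          rtol = solver$rtol %||% 1e-8,
                          atol = solver$atol %||% 1e-12,
                          method = solver$method %||% "lsoda",
                          smooth = smooth, annotate = FALSE)
    data.frame(trajectory = i, time_h = tt,
               observed = trajs[[i]]$B_dry_g,
               predicted = sim$data$B_dry_g[
                 match(round(tt, 9), round(sim$data$time_h, 9))])
  })
  pred_all <- unlist(lapply(preds, `[[`, "predicted"))
  structure(
    list(model = "dynamic", par = par,
         fixed = NULL, lower = lower, upper = upper,
         rss = results[[best]]$rss,
         r_squared = r_squared(obs, pred_all),
         n_starts = n_starts, best_start = best,
         convergence = data.frame(
           start = seq_len(nrow(starts)),
           converged = vapply(results, `[[`, logical(1), "converged"),
           rss = vapply(results, `[[`, numeric(1), "rss")),
         n_obs = n_obs, dataset_id = "trajectories",
         normalized = FALSE, seed = seed, predictions = preds),
    class = "fit_result")
}

#' Recalibrate a parameter subset on selected trajectories
#'
#' Re-estimates the masked parameters on a subset of trajectory datasets and
#' returns a new named profile variant with only those parameters changed —
#' the workflow used to carry a calibrated model over to a new feed type by
#' re-estimating the two feed half-saturations on two of the trajectories.
#'
#' @inheritParams fit_dynamic
#' @param name name for the new profile variant (default: old name +
#'   `"_recal"`).
#' @param ... further arguments passed to [fit_dynamic()].
#' @return A [parameter_profile()] with attribute `fit` (the underlying
#'   `fit_result`).
#' @export
calibrate_subset <- function(profile, trajectories, envs, mask,
                             name = NULL, ...) {
  fit <- fit_dynamic(trajectories, envs, profile, mask, ...)
  out <- profile_set(profile, as.list(fit$par), validate = TRUE)
  out$name <- name %||% paste0(profile$name, "_recal")
  out$notes <- paste0(profile$notes, " | recalibrated: ",
                      paste(mask, collapse = ", "))
  attr(out, "fit") <- fit
  out
}
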