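# Estimation workflow: data preparation, goodness of fit, static and
# dynamic least squares, rescaling and recalibration.

test_that("development times convert to rates by reciprocal", {
  expect_equal(development_time_to_rate(c(10, 20, 40)),
               c(0.1, 0.05, 0.025))
  expect_error(development_time_to_rate(c(10, 0)), "> 0")
  expect_error(development_time_to_rate(c(10, -3)), "> 0")
})

test_that("normalization scales to a unit maximum and is idempotent", {
  ds <- rate_dataset(c(1, 2), c(2, 4), "feed_density")
  nd <- normalize_dataset(ds)
  expect_equal(nd$response, c(0.5, 1))
  expect_true(nd$normalized)
  expect_equal(attr(nd, "norm_max"), 4)
  expect_equal(normalize_dataset(nd)$response, nd$response)
  expect_equal(normalize_dataset(
    rate_dataset(1, 7, "feed_density"))$response, 1)
  expect_error(normalize_dataset(
    rate_dataset(c(1, 2), c(0, 0), "feed_density")), "zero")
})

test_that("grouping pools observations with source labels and rejects
           incompatible datasets", {
  d1 <- rate_dataset(1:5, (1:5) / 5, "temperature", id = "T1")
  d2 <- rate_dataset(6:10, (5:1) / 5, "temperature", id = "T2")
  g <- group_datasets(list(d1, d2))
  expect_length(g$factor, 10)
  expect_setequal(unique(g$source_id), c("T1", "T2"))
  # normalizing per source then pooling == pooling already-normalized sets
  g2 <- group_datasets(lapply(list(d1, d2), normalize_dataset))
  expect_true(g2$normalized)
  expect_equal(max(g2$response[g2$source_id == "T1"]), 1)
  expect_equal(max(g2$response[g2$source_id == "T2"]), 1)
  expect_error(group_datasets(list()), "nonempty")
  d3 <- rate_dataset(1:5, (1:5) / 5, "moisture")
  expect_error(group_datasets(list(d1, d3)), "mixed factor")
  # pointwise averaging needs identical grids
  expect_error(group_datasets(list(d1, d2), method = "average"),
               "identical factor grids")
  avg <- group_datasets(list(d1, normalize_dataset(d1)), method = "average")
  expect_equal(avg$response, (d1$response + d1$response / max(d1$response)) / 2)
})

test_that("coefficient of determination matches hand arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")
})

test_that("static fits recover generating parameters from displaced starting
           points on noiseless data", {
  ds <- generate_response_dataset("monod_dev", prof_orig, n = 20,
                                  noise = noise_spec("none"), seed = 5)
  fit <- fit_static(ds, "monod_dev", n_starts = 8, seed = 1,
                    start = c(k_r_max_dm = 0.3, k_B_half_dm = 0.05))
  truth <- attr(ds, "true_params")[names(fit$par)]
  expect_rel_equal(fit$par, truth, 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  ds_l <- generate_response_dataset("logan10", prof_orig, n = 30,
                                    noise = noise_spec("none"), seed = 6)
  fit_l <- fit_static(ds_l, "logan10", n_starts = 24, seed = 2,
                      start = c(k_r_max_T = 0.5, k_r_base_T = 0.05,
                                k_rho_T = 0.6, k_T_max = 50,
                                k_delta_T = 10))
  expect_lt(abs(fit_l$par["k_T_max"] - 39.769), 0.1)
  expect_rel_equal(fit_l$par, attr(ds_l, "true_params")[names(fit_l$par)],
                   1e-4)
})

test_that("degenerate designs are rejected", {
  ds <- rate_dataset(rep(0.05, 6), runif(6), "feed_density")
  expect_error(fit_static(ds, "monod_dev"), "zero variance")
  ds1 <- rate_dataset(0.05, 0.5, "feed_density")
  expect_error(fit_static(ds1, "monod_dev"), "at least two")
})

test_that("fits are deterministic under a fixed seed and stable under point
           reordering", {
  ds <- generate_response_dataset("monod_grw", prof_orig, n = 25,
                                  noise = noise_spec("gaussian", 0.05),
                                  seed = 9)
  f1 <- fit_static(ds, "monod_grw", n_starts = 12, seed = 3)
  f2 <- fit_static(ds, "monod_grw", n_starts = 12, seed = 3)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$convergence, f2$convergence)
  perm <- rev(seq_along(ds$factor))
  ds_p <- rate_dataset(ds$factor[perm], ds$response[perm], ds$factor_kind)
  f3 <- fit_static(ds_p, "monod_grw", n_starts = 12, seed = 3)
  expect_rel_equal(f3$par, f1$par, 1e-8)
})

test_that("normalized fits rescale the rate parameters and only those", {
  ds <- generate_response_dataset("monod_dev", prof_orig, n = 20,
                                  noise = noise_spec("none"), seed = 5)
  nd <- normalize_dataset(ds)
  fit <- fit_static(nd, "monod_dev", n_starts = 4, seed = 1)
  sc <- rescale_to_observed(fit, attr(nd, "norm_max"))
  expect_equal(unname(sc$par["k_B_half_dm"]),
               unname(fit$par["k_B_half_dm"]))
  expect_equal(unname(sc$par["k_r_max_dm"]),
               unname(fit$par["k_r_max_dm"]) * attr(nd, "norm_max"))
  # un-normalizing recovers the absolute generating maximum rate
  expect_rel_equal(unname(sc$par["k_r_max_dm"]), 0.9758, 1e-4)
  id <- rescale_to_observed(fit, 1)
  expect_identical(id$par, fit$par)
})

test_that("dynamic fit validates its inputs", {
  obs <- data.frame(time_h = c(0, 10, 20, 30),
                    B_dry_g = c(0.002, 0.004, 0.008, 0.016))
  expect_error(fit_dynamic(obs, ref_env(), prof_recal, mask = character(0)),
               "at least one")
  expect_error(fit_dynamic(obs, ref_env(), prof_recal, mask = "k_bogus"),
               "unknown parameter symbol")
  expect_error(fit_dynamic(obs[1:3, ], ref_env(), prof_recal,
                           mask = "k_maint"), "at least 4")
})

test_that("dynamic fit recovers a perturbed maintenance rate on a short
           trajectory", {
  env <- ref_env(0.05)
  td <- generate_trajectory_dataset(prof_recal, env,
                                    times = seq(0, 300, 25),
                                    noise = noise_spec("none"), seed = 4)
  start_prof <- profile_set(prof_recal, list(k_maint = 2e-6))
  fit <- fit_dynamic(td$observations, env, start_prof, mask = "k_maint",
                     n_starts = 2, seed = 1)
  expect_rel_equal(unname(fit$par["k_maint"]), 5.6779e-6, 1e-3)
  expect_gt(fit$r_squared, 0.999)
})

test_that("recalibrating against data from the current profile is a fixed
           point, and unknown symbols are rejected", {
  env <- ref_env(0.08)
  td <- generate_trajectory_dataset(prof_recal, env,
                                    times = seq(0, 400, 25),
                                    noise = noise_spec("none"), seed = 8)
  newp <- calibrate_subset(prof_recal, td$observations, env,
                           mask = c("k_B_half_gm"), n_starts = 2, seed = 1)
  expect_rel_equal(profile_get(newp, "k_B_half_gm"),
                   profile_get(prof_recal, "k_B_half_gm"), 0.01)
  # untouched parameters are bitwise identical
  expect_identical(profile_get(newp, "k_inges"),
                   profile_get(prof_recal, "k_inges"))
  expect_identical(newp$stage, prof_recal$stage)
  expect_error(calibrate_subset(prof_recal, td$observations, env,
                                mask = "not_a_symbol"), "unknown parameter")
})
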