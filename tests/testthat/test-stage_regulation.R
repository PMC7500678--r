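# Stage-dependent regulation and combined regulators: switch identities,
# bounds, monotonicity in the drivers, and smoothing behaviour.

test_that("smooth_step has the exact logistic identities", {
  expect_equal(smooth_step(5, x0 = 5, k = 2), 0.5)
  expect_equal(smooth_step(5, x0 = 5, k = 2, direction = "descending"), 0.5)
  expect_equal(smooth_step(5 + 2 / 2, 5, 2), 1 / (1 + exp(-2)))
  expect_equal(smooth_step(1e6, 0, 1), 1)
  expect_equal(smooth_step(-1e6, 0, 1), 0)
  x <- seq(-10, 10, by = 0.1)
  expect_true(all(diff(smooth_step(x, 0, 0.7)) > 0))
  expect_error(smooth_step(1, 0, -1), "k must be")
})

test_that("ingestion potential is linear in mass and floored at zero above
           the asymptote", {
  st <- prof_orig$stage
  expect_identical(ingestion_potential(0, st), 1)
  expect_identical(ingestion_potential(st$k_B_asy, st), 0)
  expect_equal(ingestion_potential(st$k_B_asy / 2, st), 0.5)
  expect_identical(ingestion_potential(2 * st$k_B_asy, st), 0)
})

test_that("assimilation stage factor: full feeding early, ramp between the
           first two milestones, logistic midpoint at the switch centre", {
  st <- prof_orig$stage
  expect_identical(assim_stage_factor(0, 0, st), 1)
  # published milestones put the smoothed midpoint at 249.925 h
  expect_equal(st$k_T_sum_inf, 249.925)
  expect_equal(assim_stage_factor(st$k_T_sum_inf, 0, st, smooth = TRUE), 0.5)
  # piecewise: off beyond the second milestone
  expect_identical(assim_stage_factor(300, 0.01, st), 0)
  # piecewise ramp midpoint
  expect_equal(assim_stage_factor(st$k_T_sum_inf, 0, st), 0.5)
  # the ingestion potential still throttles the smoothed form
  expect_equal(assim_stage_factor(100, st$k_B_asy / 2, st, smooth = TRUE),
               0.5 * assim_stage_factor(100, 0, st, smooth = TRUE))
})

test_that("maturity factor switches off at the third milestone", {
  st <- prof_orig$stage
  expect_identical(maturity_stage_factor(100, st), 1)
  expect_identical(maturity_stage_factor(400, st), 0)
  expect_equal(maturity_stage_factor(st$k_T_sum_3, st, smooth = TRUE), 0.5)
})

test_that("combined regulators stay in [0,1] for random valid states and
           environments", {
  set.seed(7)
  for (i in 1:60) {
    env <- env_state(T_med = runif(1, 5, 50), B_feed = runif(1, 0, 0.5),
                     W_med_pct = runif(1), A_air = runif(1, 0, 5))
    T_sum <- runif(1, 0, 500)
    B <- runif(1, 0, 0.2)
    smooth <- i %% 2 == 0
    r <- regulators_at(T_sum, B, env, prof_orig, smooth)
    for (v in unlist(r)) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("assimilation regulator responds monotonically to its drivers and
           is annihilated by unviable moisture", {
  env0 <- ref_env(0.05, prof_orig)
  # non-increasing in dry mass
  b_grid <- seq(0, 0.115, length.out = 12)
  r_b <- vapply(b_grid, function(b)
    combined_assim_regulator(100, b, env0, prof_orig), numeric(1))
  expect_true(all(diff(r_b) <= 0))
  # non-decreasing in feed and airflow
  for (fld in c("B_feed", "A_air")) {
    vals <- vapply(seq(0.001, 3, length.out = 12), function(v) {
      e <- env0
      e[[fld]] <- v
      combined_assim_regulator(100, 0.01, e, prof_orig)
    }, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
  # moisture below the ingestibility threshold annihilates assimilation
  # (piecewise switches; the smoothed form leaves a small logistic tail)
  e_dry <- env_state(env0$T_med, env0$B_feed, 0.1, env0$A_air)
  expect_identical(
    combined_assim_regulator(0, 0, e_dry, prof_orig, smooth = FALSE), 0)
  expect_lt(combined_assim_regulator(0, 0, e_dry, prof_orig), 0.01)
  # single non-unit factor: temperature at 30 degC under otherwise
  # saturating conditions
  e30 <- env_state(30, 1e6, 0.725, 1e6)
  expect_equal(
    combined_assim_regulator(0, 0, e30, prof_orig, smooth = FALSE),
    0.870, tolerance = 1e-3)
})

test_that("maturity regulator ignores moisture and halves at the airflow
           half-saturation", {
  env_wet <- env_state(30, 0.05, 0.95, 2)   # lethal moisture
  env_ok <- env_state(30, 0.05, 0.60, 2)
  expect_equal(combined_mat_regulator(100, env_wet, prof_orig),
               combined_mat_regulator(100, env_ok, prof_orig))
  expect_identical(combined_mat_regulator(400, env_ok, prof_orig), 0)
  a_half <- prof_orig$airflow_monod$k_half
  e1 <- env_state(30, 0.05, 0.6, a_half)
  e2 <- env_state(30, 0.05, 0.6, a_half * 1e9)
  expect_equal(combined_mat_regulator(100, e1, prof_orig) /
                 combined_mat_regulator(100, e2, prof_orig),
               0.5, tolerance = 1e-6)
})

test_that("development regulator uses the development Monod instance and
           collapses below the thermal threshold", {
  # feed at the development half-saturation halves the regulator
  kd <- prof_orig$monod_dev$k_half
  e1 <- env_state(30, kd, 0.725, 2)
  e2 <- env_state(30, kd * 1e9, 0.725, 2)
  expect_equal(combined_dev_regulator(e1, prof_orig) /
                 combined_dev_regulator(e2, prof_orig),
               0.5, tolerance = 1e-6)
  # 10 degC is below the Logan-10 threshold: development nearly stops
  expect_lt(combined_dev_regulator(env_state(10, 1, 0.725, 2), prof_orig),
            0.06)
})

test_that("smoothed switches track the piecewise forms within the slope
           convention bounds", {
  st <- prof_orig$stage
  width <- st$k_T_sum_2 - st$k_T_sum_1
  check_band <- function(sm, pw, at, width) {
    d <- abs(sm(at) - pw(at))
    expect_lte(max(d[1:2]), 0.12)          # ramp endpoints
    expect_lte(max(d[3:4]), 0.01)          # one ramp-width outside
  }
  check_band(function(x) assim_stage_factor(x, 0, st, smooth = TRUE),
             function(x) assim_stage_factor(x, 0, st),
             c(st$k_T_sum_1, st$k_T_sum_2,
               st$k_T_sum_1 - width, st$k_T_sum_2 + width), width)
  mp <- prof_orig$moisture
  w_a <- mp$k_W_med_C2 - mp$k_W_med_C1
  check_band(function(x) moisture_assim_factor(x, mp, smooth = TRUE),
             function(x) moisture_assim_factor(x, mp),
             c(mp$k_W_med_C1, mp$k_W_med_C2,
               max(mp$k_W_med_C1 - w_a, 0),
               min(mp$k_W_med_C2 + w_a, 1)), w_a)
})
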