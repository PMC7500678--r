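# Dynamics: right-hand side structure, flux conservation, closed-form
# oracle, qualitative trajectory shape, event detection, solver convergence
# and schedule handling.

test_that("mass balance right-hand side has its structural zeros", {
  env <- ref_env(0.05, prof_orig)
  # zero mass is absorbing
  r0 <- growth_rhs(100, 0, env, prof_orig)
  expect_identical(unname(r0["dB_dry_dt"]), 0)
  # past the third milestone both regulated fluxes vanish (piecewise)
  r3 <- growth_rhs(400, 0.05, env, prof_orig, smooth = FALSE)
  expect_identical(unname(r3["dB_dry_dt"]), 0)
  # development clock never runs backwards
  expect_gte(r3["dT_sum_dt"], 0)
})

test_that("flux partition conserves the ingested mass exactly and follows
           the published fractions", {
  env <- ref_env(0.05, prof_orig)
  f <- flux_partition(100, 0.05, env, prof_orig)
  expect_equal(f$phi_B_ing, f$phi_B_excr + f$phi_B_assim + f$phi_B_eff,
               tolerance = 1e-14)
  expect_gt(f$phi_B_ing, 0)
  # effective fraction of ingested mass: 1 - 0.5762 - 0.2135
  expect_equal(f$phi_B_eff / f$phi_B_ing, 0.2103, tolerance = 1e-12)
  expect_equal(f$phi_B_metab, f$phi_B_assim + f$phi_B_mat_maint)
  # no mass, no fluxes
  f0 <- flux_partition(100, 0, env, prof_orig)
  expect_true(all(unlist(f0) == 0))
})

test_that("with constant unit regulators the simulation reproduces the
           closed-form exponential (checked at 24 h)", {
  g <- prof_orig$growth
  lambda <- (g$epsilon_inges * g$k_inges - g$k_maint) * 3600  # per hour
  tr <- simulate_larva(prof_orig, ref_env(), 24, dt_out = 0.5,
                       regulators = list(r_assim = 1, r_mat = 1, r_dev = 1))
  expect_rel_equal(tr$data$B_dry_g, 0.002 * exp(lambda * tr$data$time_h),
                   1e-6)
})

test_that("trajectory invariants hold: nonnegative mass, nondecreasing
           development sum, pointwise flux conservation", {
  tr <- simulate_larva(prof_recal, ref_env(0.05), 650)
  d <- tr$data
  expect_true(all(d$B_dry_g >= 0))
  expect_true(all(diff(d$T_sum_h) >= 0))
  resid <- abs(d$phi_B_ing - (d$phi_B_excr + d$phi_B_assim + d$phi_B_eff))
  expect_true(all(resid <= 1e-12 * pmax(d$phi_B_ing, 1e-300)))
  expect_true(all(d$r_assim >= 0 & d$r_assim <= 1))
  expect_true(all(d$r_mat >= 0 & d$r_mat <= 1))
  expect_true(all(d$r_dev >= 0 & d$r_dev <= 1))
})

test_that("unviable moisture annihilates assimilation: dry mass can only
           shrink while maintenance continues", {
  env <- env_state(30, 0.05, 0.10, 2)   # below the ingestibility threshold
  tr <- simulate_larva(prof_recal, env, 200)
  expect_true(all(diff(tr$data$B_dry_g) <= 1e-15))
  expect_lt(tr$data$B_dry_g[nrow(tr$data)], 0.002)
})

test_that("halving the solver tolerance leaves the final mass unchanged to
           1e-6 relative", {
  env <- ref_env(0.05)
  b1 <- simulate_larva(prof_recal, env, 300, rtol = 1e-8)$data$B_dry_g
  b2 <- simulate_larva(prof_recal, env, 300, rtol = 5e-9)$data$B_dry_g
  expect_rel_equal(b1[length(b1)], b2[length(b2)], 1e-6)
})

test_that("milestone crossings follow the development clock exactly under
           regulator overrides", {
  st <- prof_orig$stage
  # r_dev = 1 with the default conversion: apparent age equals real time
  tr <- simulate_larva(prof_orig, ref_env(0.05, prof_orig), 320,
                       regulators = list(r_dev = 1))
  ev <- tr$events
  expect_equal(ev$time_h[ev$event == "k_T_sum_3"], st$k_T_sum_3,
               tolerance = 1e-5)
  # r_dev = 0.5 doubles every crossing time
  tr2 <- simulate_larva(prof_orig, ref_env(0.05, prof_orig), 650,
                        regulators = list(r_dev = 0.5))
  ev2 <- tr2$events
  expect_equal(ev2$time_h[ev2$event == "k_T_sum_1"], 2 * st$k_T_sum_1,
               tolerance = 1e-4)
  expect_equal(ev2$time_h[ev2$event == "k_T_sum_3"], 2 * st$k_T_sum_3,
               tolerance = 1e-4)
  # milestones beyond the simulated span are absent
  tr3 <- simulate_larva(prof_orig, ref_env(0.05, prof_orig), 100,
                        regulators = list(r_dev = 1))
  expect_false("k_T_sum_3" %in% tr3$events$event)
})

test_that("environment schedules hold between samples and support linear
           interpolation", {
  sch <- environment_schedule(c(0, 100, 200), T_med = c(20, 30, 25),
                              B_feed = 0.05, W_med_pct = 0.7, A_air = 2)
  expect_equal(env_at(sch, 50)$T_med, 20)      # hold
  expect_equal(env_at(sch, 150, "linear")$T_med, 27.5)
  expect_equal(env_at(sch, 500)$T_med, 25)     # hold beyond last sample
  expect_error(environment_schedule(c(0, 50, 50), 20, 0.05, 0.7, 2),
               "strictly increasing")
  # a step up in temperature accelerates development relative to constant
  # cold conditions
  cold <- simulate_larva(prof_recal, env_state(18, 0.05, 0.72, 2), 300)
  warm_late <- simulate_larva(
    prof_recal,
    environment_schedule(c(0, 150), T_med = c(18, 32), B_feed = 0.05,
                         W_med_pct = 0.72, A_air = 2), 300)
  expect_gt(max(warm_late$data$T_sum_h), max(cold$data$T_sum_h))
})

test_that("more feed never lowers the peak dry mass", {
  peaks <- vapply(c(0.01, 0.05, 0.2), function(f) {
    max(simulate_larva(prof_recal, ref_env(f), 400)$data$B_dry_g)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("trajectory export round-trips through CSV", {
  tr <- simulate_larva(prof_recal, ref_env(0.05), 50, dt_out = 5)
  csv <- tempfile(fileext = ".csv")
  ecsv <- tempfile(fileext = ".csv")
  write_trajectory(tr, csv, ecsv)
  back <- read.csv(csv)
  expect_identical(names(back), names(tr$data))
  expect_equal(back$B_dry_g, tr$data$B_dry_g, tolerance = 1e-15)
  expect_true("B_dry_peak" %in% read.csv(ecsv)$event)
})
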