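# Profiles, file formats and the command-line entry point.

test_that("shipped profiles carry the published estimates and pass
           validation", {
  expect_equal(profile_get(prof_orig, "k_T_max"), 39.769)
  expect_equal(profile_get(prof_orig, "k_T_sum_3"), 297.5)
  expect_equal(profile_get(prof_orig, "k_inges"), 1.61e-4)
  expect_equal(profile_get(prof_orig, "k_B_half_dm"), 0.0049)
  expect_equal(profile_get(prof_orig, "k_B_half_gm"), 0.00532)
  expect_equal(profile_get(prof_recal, "k_B_half_dm"), 0.0137)
  expect_equal(profile_get(prof_recal, "k_B_half_gm"), 0.0717)
  expect_silent(validate_profile(prof_orig))
  expect_silent(validate_profile(prof_recal))
  # every advertised symbol resolves
  for (s in profile_symbols()) {
    expect_true(is.numeric(profile_get(prof_orig, s)), label = s)
  }
  expect_error(load_profile("no_such_profile"), "unknown profile")
})

test_that("the digestion-efficiency inconsistency is carried explicitly and
           the strict mass-balance mode derives it from the fractions", {
  expect_equal(prof_orig$growth$epsilon_inges, 0.79)
  expect_false(prof_orig$growth$epsilon_consistent)
  strict <- growth_params(1.61e-4, 5.6779e-6, epsilon_inges = NULL,
                          k_alpha_excr = 0.5762, k_alpha_assim = 0.2135)
  expect_equal(strict$epsilon_inges, 0.2103)
  expect_true(strict$epsilon_consistent)
})

test_that("profile YAML round trip is lossless and invalid files name the
           offending component", {
  path <- tempfile(fileext = ".yaml")
  write_profile(prof_recal, path)
  back <- read_profile(path)
  for (s in profile_symbols()) {
    expect_identical(profile_get(back, s), profile_get(prof_recal, s),
                     label = s)
  }
  expect_identical(back$name, prof_recal$name)
  # corrupt the stage ordering
  txt <- readLines(path)
  txt <- sub("k_T_sum_2: .*", "k_T_sum_2: 100.0", txt)
  bad <- tempfile(fileext = ".yaml")
  writeLines(txt, bad)
  expect_error(read_profile(bad), "stage_params")
})

test_that("profile_set updates derived quantities and validates ordering", {
  p2 <- profile_set(prof_orig, list(k_T_sum_1 = 200, k_T_sum_2 = 280))
  expect_equal(p2$stage$k_T_sum_inf, 240)
  expect_error(profile_set(prof_orig, list(k_T_sum_1 = 280)),
               "k_T_sum_1 < k_T_sum_2")
  expect_error(profile_set(prof_orig, list(nonsense = 1)),
               "unknown parameter symbol")
})

test_that("schedule and dataset CSVs round trip losslessly and malformed
           files are rejected with a named column", {
  sch <- environment_schedule(c(0, 10.5, 100) + pi * 1e-3,
                              T_med = c(20.1, 29.9, 31),
                              B_feed = c(0.05, 0.06, 0.07),
                              W_med_pct = 0.713, A_air = 1.9)
  path <- tempfile(fileext = ".csv")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_identical(back$data, sch$data)
  # missing column
  df <- read.csv(path)
  df$A_air_l_min <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_error(read_schedule(path2), "A_air_l_min")
  # non-monotone time stamps
  df2 <- read.csv(path)
  df2$time_h <- c(0, 50, 10)
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_schedule(path2), "strictly increasing")

  ds <- generate_response_dataset("moisture", prof_orig, n = 12, seed = 2)
  dpath <- tempfile(fileext = ".csv")
  write_dataset(ds, dpath)
  ds_back <- read_dataset(dpath)
  expect_identical(ds_back$factor, ds$factor)
  expect_identical(ds_back$response, ds$response)
  expect_identical(ds_back$factor_kind, "moisture")
})

test_that("the command-line interface runs its subcommands and signals
           usage errors", {
  # half-saturation identity through `evaluate`
  out <- capture.output(
    status <- bsf_cli(c("evaluate", "--model", "monod_dev", "--at",
                        "0.0049")))
  expect_identical(status, 0L)
  expect_equal(as.numeric(strsplit(out[2], ",")[[1]][2]), 0.9758 / 2,
               tolerance = 1e-12)
  # unknown subcommand: usage error
  expect_identical(suppressMessages(bsf_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(bsf_cli(character(0))), 2L)
  # missing required option: runtime error, message on stderr
  expect_identical(suppressMessages(bsf_cli(c("simulate", "--temp", "30"))),
                   1L)
  # simulate writes a trajectory and an event table with the completed
  # development milestone
  tcsv <- tempfile(fileext = ".csv")
  ecsv <- tempfile(fileext = ".csv")
  status <- suppressMessages(
    bsf_cli(c("simulate", "--temp", "31", "--feed", "0.05", "--moisture",
              "0.72", "--airflow", "2", "--t-end", "650",
              "--out", tcsv, "--events-out", ecsv)))
  expect_identical(status, 0L)
  ev <- read.csv(ecsv)
  expect_true("k_T_sum_3" %in% ev$event)
  # fit subcommand on a generated fixture
  fixdir <- file.path(tempdir(), "clifix")
  suppressMessages(bsf_cli(c("generate", "--out-dir", fixdir, "--seed",
                             "4")))
  report <- tempfile(fileext = ".txt")
  status <- suppressMessages(
    bsf_cli(c("fit", "--data", file.path(fixdir, "F1_grw.csv"), "--model",
              "monod_grw", "--n-starts", "6", "--seed", "2", "--out",
              report)))
  expect_identical(status, 0L)
  lines <- readLines(report)
  expect_true(any(grepl("^r_squared: ", lines)))
  r2 <- as.numeric(sub("^r_squared: ", "",
                       lines[grepl("^r_squared: ", lines)]))
  expect_gt(r2, 0.9)
  unlink(fixdir, recursive = TRUE)
})
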