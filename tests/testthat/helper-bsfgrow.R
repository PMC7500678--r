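# Shared fixtures: the two shipped profiles and a favourable constant
# rearing environment used across tests. Everything is rebuilt from code;
# no stored data.

prof_orig <- load_profile("table3_original")
prof_recal <- load_profile("table3_recalibrated_D1D5")

# Moderate feed-limited ration near the optimum of every other factor: the
# regime of the feeding-rate trajectory experiments.
ref_env <- function(feed = 0.05, profile = prof_recal) {
  reference_env(profile, B_feed = feed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-300)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-300)), tol))
}
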