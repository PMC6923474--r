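# Trapping-protocol analysis on simulated recordings.  The generating
# schemes: full trapping (no escape from the closed-blocked state),
# partial trapping (slow escape), sequential (closure forbidden while
# blocked, hence a washout tail).

make_trapping_traces <- function(rates, t_ap5 = c(0.5, 2, 4), n_cells = 2,
                                 seed = 1, noise_sd = 0) {
  fx <- make_study_fixtures(study_config(
    "trapping", rates = rates, ca_levels = 0.25, n_cells = n_cells,
    noise_sd = noise_sd, t_ap5 = t_ap5,
    jitter_rates = if (noise_sd > 0) 0.05 else 0,
    jitter_conductance = 0.15), seed = seed)
  fx
}

test_that("no escape: fast fraction flat in washout duration, classified full trapping", {
  fx <- make_trapping_traces(rate_set_trapping(k_escape = 0), seed = 21)
  res <- analyze_trapping(fx$traces, cells = fx$manifest$cell)
  expect_equal(res$mode, "full_trapping")
  expect_false(res$tail_detected)
  fr <- res$per_washout$fraction
  expect_lt(max(fr) - min(fr), 0.05)
  expect_true(is.na(res$escape_rate))
})

test_that("slow escape: fraction recovers monotonically, partial trapping, rate recovered", {
  fx <- make_trapping_traces(rate_set_trapping(k_escape = 0.25), seed = 22)
  res <- analyze_trapping(fx$traces, cells = fx$manifest$cell)
  expect_equal(res$mode, "partial_trapping")
  expect_false(res$tail_detected)
  expect_true(all(diff(res$per_washout$fraction) > 0))
  expect_equal(res$escape_rate, 0.25, tolerance = 0.2)
})

test_that("sequential blocker: washout tail, classified sequential", {
  fx <- make_trapping_traces(rate_set_sequential(), seed = 23)
  res <- analyze_trapping(fx$traces, cells = fx$manifest$cell)
  expect_true(res$tail_detected)
  expect_equal(res$mode, "sequential")
})

test_that("classification rules are as stated, including the contradictory case", {
  expect_equal(classify_block_mode(TRUE, list(flat = FALSE, amplitude = 0.4)),
               "sequential")
  expect_equal(classify_block_mode(FALSE, list(flat = TRUE, amplitude = 0.01)),
               "full_trapping")
  expect_equal(classify_block_mode(FALSE, list(flat = FALSE, amplitude = 0.4)),
               "partial_trapping")
  expect_equal(classify_block_mode(TRUE, list(flat = TRUE, amplitude = 0.01)),
               "indeterminate")
})

test_that("analysis refuses a single washout duration", {
  fx <- make_trapping_traces(rate_set_trapping(), t_ap5 = 2, seed = 24)
  expect_error(analyze_trapping(fx$traces, cells = fx$manifest$cell),
               class = "nmdarblock_validation_error")
})

test_that("tau_s is invariant across washout durations for a single unblock rate", {
  fx <- make_trapping_traces(rate_set_trapping(k_escape = 0.25),
                             t_ap5 = c(0.5, 1, 2, 4), n_cells = 2, seed = 25,
                             noise_sd = 3)
  res <- analyze_trapping(fx$traces, cells = fx$manifest$cell)
  expect_false(is.null(res$tau_s_anova))
  expect_gt(res$tau_s_anova$p, 0.05)
  # spread of group-mean tau_s stays within 15% of the overall mean
  taus <- res$per_washout$tau_s
  expect_lt((max(taus) - min(taus)) / mean(taus), 0.15)
})
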