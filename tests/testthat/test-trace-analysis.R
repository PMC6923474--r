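test_that("blocked fraction follows 1 - I_b/I_c and warns on sign mismatch", {
  expect_equal(blocked_fraction(-100, -50), 0.5)
  expect_equal(blocked_fraction(-80, -80), 0)
  expect_error(blocked_fraction(0, -50), class = "nmdarblock_validation_error")
  expect_warning(blocked_fraction(-100, 10), "opposite signs")
})

test_that("mono-exponential fit recovers an exact generated relaxation", {
  t <- seq(0, 12, by = 0.01)
  y <- (-800 - (-200)) * exp(-t / 2.75) + (-200)
  f <- fit_monoexp(t, y)
  expect_equal(f$tau, 2.75, tolerance = 1e-6)
  expect_equal(f$i_max, -800, tolerance = 1e-6)
  expect_equal(f$i_min, -200, tolerance = 1e-6)
  expect_lt(f$rms, 1e-8)
  expect_false(f$at_bound)
})

test_that("block-onset relaxation at 0 mV gives 1/tau = k_on*B + k_off = 0.364 1/s", {
  # e_rev raised so a driving force remains at 0 mV holding potential
  r <- rate_set_pure_block(e_rev = 40)  # voltage-independent 0.0016 / 0.204
  tr <- simulate_trace(r, short_block_step(100, vm = 0))
  f <- fit_epoch_relaxation(tr, 3)
  expect_equal(1 / f$tau, 0.364, tolerance = 0.01)
})

test_that("steady-state windows avoid the exchange transient and flag drift", {
  r <- rate_set_pure_block()
  tr <- simulate_trace(r, short_block_step(100))
  e <- tr$protocol$epochs[2, ]
  m <- measure_steady_state(tr, 2, tau_exchange = 0.01)
  expect_true(m$steady)
  # all samples in the window are at least 3 exchange constants from the edge
  expect_gte(e$t_end - m$window, e$t_start + 3 * 0.01)
  # a window covering the relaxing segment is flagged unsteady
  m2 <- measure_steady_state(tr, 3, window_frac = 0.999, tau_exchange = 0.01)
  expect_false(m2$steady)
})

test_that("bi-exponential rise recovery: exact amplitudes within 2% and degenerate flagging", {
  t <- seq(0, 40, by = 0.01)
  i_b <- 30
  y <- -(400 * (1 - exp(-t / 0.05)) + 600 * (1 - exp(-t / 13)) + i_b)
  f <- fit_biexp_rise(t, y, i_b)
  expect_equal(f$tau_f, 0.05, tolerance = 0.02)
  expect_equal(f$tau_s, 13, tolerance = 0.02)
  expect_equal(f$i_f, 400, tolerance = 0.02)
  expect_equal(f$i_s, 600, tolerance = 0.02)
  expect_equal(f$c, 400 + 600 + i_b, tolerance = 0.02)
  expect_false(f$degenerate)
  # tau ratio < 3: degenerate, with a single-exponential fallback
  y2 <- -(400 * (1 - exp(-t / 4)) + 600 * (1 - exp(-t / 8)) + i_b)
  f2 <- fit_biexp_rise(t, y2, i_b)
  expect_true(f2$degenerate)
  expect_s3_class(f2$fallback, "relaxation_fit")
})

test_that("tail currents appear for sequential block only", {
  p <- protocol_trapping(t_ap5 = 2, atl = 200, sample_rate = 200)
  # trapping blocker: closure with the blocker bound, no tail
  tr_trap <- simulate_trace(rate_set_trapping(k_escape = 0.25), p)
  te <- nmdarblock:::trapping_epochs(tr_trap$protocol)
  expect_false(detect_tail_current(tr_trap, te$washout)$tail)
  # sequential blocker: closure forbidden while blocked, washout tail
  tr_seq <- simulate_trace(rate_set_sequential(), p)
  d <- detect_tail_current(tr_seq, te$washout)
  expect_true(d$tail)
  expect_gt(d$area, 0)
  # no blocker at all: nothing to generate a tail
  p0 <- protocol_trapping(t_ap5 = 2, atl = 0.0, sample_rate = 200)
  # ATL = 0 is not a valid trapping protocol epoch set; use a plain washout
  p0 <- protocol(rbind(solution_epoch(0, 1, Ca_out = 0.25),
                       solution_epoch(1, 6, NMDA = 100, Gly = 30, Ca_out = 0.25),
                       solution_epoch(6, 10, Ca_out = 0.25)), sample_rate = 200)
  tr0 <- simulate_trace(rate_set_trapping(), p0)
  expect_false(detect_tail_current(tr0, 3)$tail)
})
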