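test_that("no agonist means no current; noiseless traces are bit-for-bit reproducible", {
  r <- rate_set()
  p <- protocol(rbind(solution_epoch(0, 2, Ca_out = 1),
                      solution_epoch(2, 4, ATL = 100, Ca_out = 1)),
                sample_rate = 100)
  tr <- simulate_trace(r, p)
  expect_equal(max(abs(tr$current)), 0, tolerance = 1e-12)
  p2 <- protocol_block_step(50, sample_rate = 25, control_duration = 5,
                            on_duration = 5, off_duration = 5)
  a <- simulate_trace(r, p2)
  b <- simulate_trace(r, p2)
  expect_identical(a$current, b$current)
  # noisy traces reproduce given the seed and differ across seeds
  n1 <- simulate_trace(r, p2, noise_sd = 5, seed = 42)
  n2 <- simulate_trace(r, p2, noise_sd = 5, seed = 42)
  n3 <- simulate_trace(r, p2, noise_sd = 5, seed = 43)
  expect_identical(n1$current, n2$current)
  expect_false(identical(n1$current, n3$current))
})

test_that("occupancies stay on the probability simplex for random valid rate sets", {
  set.seed(101)
  for (i in 1:5) {
    r <- rate_set(alpha_close = runif(1, 1, 80),
                  beta_open_max = runif(1, 10, 200),
                  k_des0 = runif(1, 0, 1), k_rec = runif(1, 0.1, 2),
                  atl_des_gain = runif(1, 0, 10), atl_des_k = runif(1, 0.5, 10),
                  k_on0 = 10^runif(1, -4, -1), k_off0 = runif(1, 0.05, 1),
                  delta_block = runif(1), k_escape = runif(1, 0, 0.5))
    p <- protocol_block_step(runif(1, 5, 300), ca_out = runif(1, 0.25, 4),
                             vm = runif(1, -100, 40), baseline = 1,
                             control_duration = 4, on_duration = 6,
                             off_duration = 4, sample_rate = 50)
    tr <- simulate_trace(r, p, return_states = TRUE)
    expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
  }
})

test_that("pure-block simulation matches the two-state closed forms", {
  # steady state: I_b/I_c = Kd/(Kd+B); relaxation: 1/tau = k_on*B + k_off
  r <- rate_set_pure_block()  # k_on 0.0016, k_off 0.204, Kd 127.5 at all Vm
  for (b in c(50, 200)) {
    p <- protocol_block_step(b, sample_rate = 25)
    tr <- simulate_trace(r, p)
    base <- baseline_current(tr)
    i_c <- measure_steady_state(tr, 2, baseline = base)$mean
    i_b <- measure_steady_state(tr, 3, baseline = base)$mean
    expect_equal(i_b / i_c, two_state_rel_amplitude(b, 0.0016, 0.204),
                 tolerance = 0.01)
    f_on <- fit_epoch_relaxation(tr, 3)
    expect_equal(1 / f_on$tau, two_state_rate(b, 0.0016, 0.204),
                 tolerance = 0.01)
    f_off <- fit_epoch_relaxation(tr, 4)
    expect_equal(1 / f_off$tau, 0.204, tolerance = 0.01)
  }
})

test_that("unblock time constant does not depend on the prior blocker concentration", {
  r <- rate_set_pure_block()
  taus <- vapply(c(10, 100, 500), function(b) {
    tr <- simulate_trace(r, protocol_block_step(b, sample_rate = 25))
    fit_epoch_relaxation(tr, 4)$tau
  }, numeric(1))
  expect_lt(max(taus) / min(taus) - 1, 0.02)
})

test_that("fixture sets are reproducible, carry ground truth, and refuse n < 2", {
  cfg <- study_config("staircase", rates = rate_set_pure_block(),
                      ca_levels = 0.25, n_cells = 2, noise_sd = 3,
                      atl_levels = c(30, 100, 300), sample_rate = 25)
  fa <- make_study_fixtures(cfg, seed = 9)
  fb <- make_study_fixtures(cfg, seed = 9)
  expect_identical(lapply(fa$traces, `[[`, "current"),
                   lapply(fb$traces, `[[`, "current"))
  expect_equal(nrow(fa$manifest), 2)
  expect_true(all(c("rates", "vm", "ca_out") %in% names(fa$ground_truth[[1]])))
  expect_error(study_config("staircase", n_cells = 1),
               class = "nmdarblock_validation_error")
})
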