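test_that("rate matrix rows balance and blocker-free schemes have no blocked flux", {
  r <- rate_set()
  sol <- list(NMDA = 100, Gly = 30, ATL = 0, AP5 = 0, Ca_out = 1)
  q <- build_rate_matrix(r, sol, vm = -70)
  expect_equal(rowSums(q), setNames(rep(0, 5), NMDAR_STATES), tolerance = 1e-12)
  expect_true(all(q[row(q) != col(q)] >= 0))
  # no blocker anywhere: nothing flows into OB or CB
  expect_identical(unname(q["O", "OB"]), 0)
  expect_identical(unname(q[, "CB"][c("C", "O", "D")]), c(0, 0, 0))
})

test_that("voltage factor on the block on-rate follows the Woodhull exponential", {
  r <- rate_set(delta_block = 0.51, z_block = 1, rt_over_f = 25.7, k_on0 = 0.0016)
  sol <- list(NMDA = 100, Gly = 30, ATL = 50, AP5 = 0, Ca_out = 0.25)
  q0 <- build_rate_matrix(r, sol, vm = 0)
  # at 0 mV the on-rate is exactly k_on0 * ATL
  expect_equal(unname(q0["O", "OB"]), 0.0016 * 50, tolerance = 1e-12)
  qh <- build_rate_matrix(r, sol, vm = -70)
  expect_equal(unname(qh["O", "OB"] / q0["O", "OB"]), exp(0.51 * 70 / 25.7),
               tolerance = 1e-12)
  expect_equal(unname(qh["O", "OB"] / q0["O", "OB"]), 4.00, tolerance = 0.005)
})

test_that("AP5 shuts off activation and invalid inputs are rejected", {
  r <- rate_set()
  q <- build_rate_matrix(r, list(NMDA = 100, Gly = 30, ATL = 0, AP5 = 50,
                                 Ca_out = 1), vm = -70)
  expect_identical(unname(q["C", "O"]), 0)
  expect_identical(unname(q["CB", "OB"]), 0)
  expect_error(build_rate_matrix(r, list(NMDA = -1, Ca_out = 1), vm = -70),
               class = "nmdarblock_validation_error")
  expect_error(rate_set(k_off0 = -0.1), class = "nmdarblock_validation_error")
  expect_error(rate_set(delta_block = 1.4), class = "nmdarblock_validation_error")
  expect_error(rate_set(bapta_factor = 2), class = "nmdarblock_validation_error")
})

test_that("desensitization scales with calcium influx and is silenced by BAPTA", {
  r <- rate_set(bapta_factor = 0)
  sol <- function(ca) list(NMDA = 100, Gly = 30, ATL = 0, AP5 = 0, Ca_out = ca)
  q1 <- build_rate_matrix(r, sol(1), vm = -70)
  q2 <- build_rate_matrix(r, sol(2), vm = -70)
  expect_equal(unname(q2["O", "D"] / q1["O", "D"]), 2, tolerance = 1e-12)
  # influx surrogate normalized to Ca_out at -70 mV
  expect_equal(unname(q1["O", "D"]), r$k_des0 * r$ca_coupling * 1, tolerance = 1e-12)
  # driving force vanishes at the reversal potential
  q0 <- build_rate_matrix(r, sol(1), vm = r$e_rev)
  expect_identical(unname(q0["O", "D"]), 0)
  qb <- build_rate_matrix(r, sol(1), vm = -70, bapta = TRUE)
  expect_identical(unname(qb["O", "D"]), 0)
})

test_that("stationary occupancy matches the detailed-balance solution of the block tree", {
  # with k_des0 = 0 and k_escape = 0 the scheme is a tree:
  # P_O/P_C = k_open/alpha, P_OB/P_O = B/Kd, P_CB/P_OB = alpha/k_open
  r <- rate_set_pure_block()
  b <- 60
  sol <- list(NMDA = 100, Gly = 30, ATL = b, AP5 = 0, Ca_out = 0.25)
  p <- steady_state_occupancy(r, sol, vm = -70)
  k_open <- r$beta_open_max * 100 / 130
  kd <- r$k_off0 / r$k_on0
  expect_equal(p[["O"]] / p[["C"]], k_open / r$alpha_close, tolerance = 1e-9)
  expect_equal(p[["OB"]] / p[["O"]], b / kd, tolerance = 1e-9)
  expect_equal(p[["CB"]] / p[["OB"]], r$alpha_close / k_open, tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})
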