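test_that("epoch validation enforces ordering, overlap and sign rules", {
  expect_error(solution_epoch(5, 4, NMDA = 100, Ca_out = 1),
               class = "nmdarblock_epoch_error")
  expect_error(solution_epoch(0, 5, NMDA = -1, Ca_out = 1),
               class = "nmdarblock_epoch_error")
  eps <- rbind(solution_epoch(0, 5, Ca_out = 1),
               solution_epoch(4, 8, NMDA = 100, Ca_out = 1))
  expect_error(protocol(eps), class = "nmdarblock_epoch_error")
  eps_ok <- rbind(solution_epoch(0, 5, Ca_out = 1),
                  solution_epoch(5, 8, NMDA = 100, Ca_out = 1))
  p <- protocol(eps_ok, holding_voltage = -70)
  expect_s3_class(p, "protocol")
  expect_equal(p$total_duration, 8)
  expect_error(protocol(eps_ok, total_duration = 6),
               class = "nmdarblock_epoch_error")
})

test_that("solution exchange lags concentrations with the first-order time constant", {
  p <- protocol(rbind(solution_epoch(0, 1, Ca_out = 1),
                      solution_epoch(1, 3, NMDA = 100, Gly = 30, Ca_out = 1)))
  sc <- nmdarblock:::solution_time_course(p, tau = 0.01)
  # one time constant after the step: 1 - 1/e of the target
  c1 <- sc$conc(1.01)
  expect_equal(unname(c1["NMDA"]), 100 * (1 - exp(-1)), tolerance = 1e-9)
  # ten time constants: essentially complete
  expect_equal(unname(sc$conc(1.1)["NMDA"]), 100, tolerance = 1e-4)
  # instantaneous exchange
  sc0 <- nmdarblock:::solution_time_course(p, tau = 0)
  expect_equal(unname(sc0$conc(1.0001)["NMDA"]), 100)
})

test_that("AP5 follows the nominal application rather than the exchange lag", {
  p <- protocol_trapping(t_ap5 = 1, atl = 200, sample_rate = 100)
  sc <- nmdarblock:::solution_time_course(p, tau = 0.01)
  wash_start <- p$epochs$t_start[4]
  test_start <- p$epochs$t_start[5]
  expect_equal(unname(sc$conc(wash_start + 0.001)["AP5"]), 50)
  expect_identical(unname(sc$conc(test_start + 0.001)["AP5"]), 0)
  # the blocker, in contrast, is still washing out just after the switch
  expect_gt(unname(sc$conc(wash_start + 0.001)["ATL"]), 100)
})

test_that("gaps between epochs keep the bath calcium and clear the drugs", {
  eps <- rbind(solution_epoch(0, 2, NMDA = 100, ATL = 50, Ca_out = 2),
               solution_epoch(5, 6, NMDA = 100, Ca_out = 2))
  p <- protocol(eps, total_duration = 6)
  sc <- nmdarblock:::solution_time_course(p, tau = 0)
  mid <- sc$conc(3.5)
  expect_identical(unname(mid["NMDA"]), 0)
  expect_identical(unname(mid["ATL"]), 0)
  expect_identical(unname(mid["Ca_out"]), 2)
})
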