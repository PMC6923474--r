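test_that("Woodhull fit is exact on data generated from the printed voltage relation", {
  vm <- c(-100, -70, -30)
  ic50 <- 220 * exp(vm * 0.021)
  f <- fit_woodhull(vm, ic50)
  expect_equal(f$ic50_0mv, 220, tolerance = 1e-6)
  expect_equal(f$e_fold_mv, 1 / 0.021, tolerance = 1e-6)  # 47.6 mV
  expect_equal(f$delta, 0.021 * 25.7, tolerance = 1e-6)
  expect_false(f$voltage_independent)
})

test_that("the printed 50 mV e-fold voltage implies an electrical depth of 0.51", {
  expect_equal(round(woodhull_delta(50), 2), 0.51)
})

test_that("voltage-independent IC50s are flagged and wrong-signed slopes rejected", {
  vm <- c(-100, -70, -30, 0)
  f <- fit_woodhull(vm, c(100, 100.2, 99.9, 100.1))
  expect_true(f$voltage_independent)
  expect_error(fit_woodhull(vm, 100 * exp(-vm * 0.03)),
               "sign-convention")
  expect_error(fit_woodhull(c(-70, -70, -30), c(10, 11, 20)),
               class = "nmdarblock_validation_error")
})

test_that("calcium-exponential fit is exact on generated data and flags flat input", {
  ca <- c(0.25, 0.5, 1, 2, 4)
  f <- fit_ca_exponential(ca, 91 * exp(-ca / 0.63))
  expect_equal(f$a, 91, tolerance = 1e-6)
  expect_equal(f$b, 0.63, tolerance = 1e-6)
  expect_false(f$flat)
  set.seed(2)
  fflat <- fit_ca_exponential(ca, 120 * exp(rnorm(5, 0, 0.02)))
  expect_true(fflat$flat)
  expect_warning(fit_ca_exponential(ca, c(60, 90, 30, 10, 3)), "non-monotonic")
})

test_that("refit of the condition-mean IC50 series recovers the published exponential", {
  ref <- atl_reference_values()$ic50_by_ca
  f <- fit_ca_exponential(ref$ca, ref$ic50)
  expect_equal(f$b, 0.63, tolerance = 0.10)
  expect_equal(f$a, 91, tolerance = 0.10)
})

test_that("surface fit recovers generated parameters exactly and rejects rank-deficient input", {
  g <- expand.grid(vm = c(-100, -70, -30, 0), ca = c(0.25, 0.5, 1, 2, 4))
  g$ic50 <- 317 * exp(0.018 * g$vm - g$ca / 0.69)
  f <- fit_surface(g)
  expect_equal(f$prefactor, 317, tolerance = 1e-6)
  expect_equal(f$a, 0.018, tolerance = 1e-6)
  expect_equal(f$b, 0.69, tolerance = 1e-6)
  expect_equal(f$delta_implied, 0.018 * 25.7, tolerance = 1e-6)
  expect_error(fit_surface(data.frame(vm = -70, ca = c(1, 2, 4),
                                      ic50 = c(20, 5, 1))),
               class = "nmdarblock_validation_error")
})

test_that("separability: product-model slices give the same a and b whatever the design", {
  full <- expand.grid(vm = c(-100, -70, -30), ca = c(0.25, 1, 4))
  full$ic50 <- 250 * exp(0.02 * full$vm - full$ca / 0.8)
  f_full <- fit_surface(full)
  sub <- full[full$ca %in% c(0.25, 4) | full$vm == -70, ]
  f_sub <- fit_surface(sub)
  expect_equal(f_sub$a, f_full$a, tolerance = 1e-9)
  expect_equal(f_sub$b, f_full$b, tolerance = 1e-9)
})

test_that("the composed prefactor and surface predictions match direct evaluation", {
  expect_equal(compose_prefactor(220, 91, 63), 317.78, tolerance = 0.001)
  s <- list(prefactor = 317, a = 0.018, b = 0.69)
  expect_equal(predict_ic50(s, 0, 0.25), 317 * exp(-0.25 / 0.69))
  expect_equal(predict_ic50(s, 0, 0.25), 220.6, tolerance = 0.005)
  expect_equal(predict_ic50(s, 0, 0), 317)
  # monotone decreasing in calcium at fixed voltage
  ic <- predict_ic50(s, -70, c(0.25, 1, 2, 4))
  expect_true(all(diff(ic) < 0))
  g <- surface_grid(s, vm = c(-70, 0), ca = c(0.25, 4))
  expect_equal(nrow(g), 4)
})
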