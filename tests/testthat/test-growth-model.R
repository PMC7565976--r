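test_that("caliper volume follows the ellipsoid formula and rejects bad input", {
  expect_equal(volume_from_caliper(10, 4), 80)
  expect_equal(volume_from_caliper(5, 0), 0)
  expect_equal(volume_from_caliper(2, 2), 4)
  expect_equal(volume_from_caliper(c(10, 2), c(4, 2)), c(80, 4))
  expect_error(volume_from_caliper(4, 10), "L must be >=")
  expect_error(volume_from_caliper(5, -1), "non-negative")
  expect_error(volume_from_caliper(NA_real_, 1), "finite")
})

test_that("effective growth rate scales by 1 - eff under treatment", {
  expect_equal(effective_growth_rate(0.64, 0, treated = TRUE), 0.64)
  expect_equal(effective_growth_rate(0.64, 0.52, treated = TRUE),
               0.64 * 0.48)
  ## untreated-to-treated ratio ~ factor 2 at the study's effect size
  expect_equal(0.64 / effective_growth_rate(0.64, 0.52, treated = TRUE),
               1 / 0.48)
  expect_equal(round(1 / 0.48), 2)
  expect_equal(effective_growth_rate(0.64, 0.52, treated = FALSE), 0.64)
  ## growth arrest only in shrinkage mode
  expect_error(effective_growth_rate(0.64, 1, treated = TRUE), "shrinkage")
  expect_equal(effective_growth_rate(0.64, 1, treated = TRUE,
                                     shrinkage = TRUE), 0)
  expect_error(effective_growth_rate(-1, 0, treated = FALSE), "k_growth")
  expect_error(effective_growth_rate(1, -0.1, treated = FALSE), "eff")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(gompertz_params(0.6, 1000, v0 = 1200), "v0 must not exceed")
  expect_error(gompertz_params(-0.6, 1000, v0 = 80), "k_growth")
  expect_error(gompertz_params(0.6, 1000, gamma = 0, v0 = 80), "gamma")
  expect_error(treatment_schedule(TRUE, start_time = -1), "start_time")
  expect_error(treatment_schedule(TRUE, dosing_interval = 0),
               "dosing_interval")
  expect_silent(gompertz_params(0.64, 1620, 0.17, 0.52, 80))
})

test_that("trajectory honours initial condition and plateau fixed point", {
  p <- gompertz_params(0.64, 1620, gamma = 0.17, v0 = 80)
  expect_equal(predict_volume(p, times = 0), 80)
  pfix <- gompertz_params(0.5, 500, gamma = 0.5, v0 = 500)
  expect_equal(predict_volume(pfix, times = c(0, 5, 20)), rep(500, 3))
  expect_error(predict_volume(p, times = c(3, 1)), "sorted")
  expect_error(predict_volume(p, times = -1), "non-negative")
})

test_that("classic Gompertz (gamma = 1) matches the closed form", {
  t <- seq(0, 50, by = 0.5)
  p <- gompertz_params(0.64, 1620, gamma = 1, v0 = 80)
  oracle <- gompertz_closed_form(t, 80, 1620, 0.64)
  expect_equal(predict_volume(p, times = t), oracle, tolerance = 1e-10)
  expect_equal(predict_volume(p, times = t, method = "ode"), oracle,
               tolerance = 1e-6)
  ## the value at day 2 is ~7.0e2 mm^3
  expect_equal(predict_volume(p, times = 2), 701.9079, tolerance = 1e-6)
})

test_that("numeric and analytic solutions agree for general gamma", {
  t <- seq(0, 50, by = 1)
  for (g in c(0.17, 0.6, 1.7)) {
    p <- gompertz_params(0.64, 1620, gamma = g, eff = 0.52, v0 = 80)
    s <- treatment_schedule(TRUE, start_time = 7)
    va <- predict_volume(p, s, times = t)
    vo <- predict_volume(p, s, times = t, method = "ode")
    expect_equal(va, vo, tolerance = 1e-6)
  }
})

test_that("trajectories are monotone, bounded, and slowed by treatment", {
  t <- seq(0, 40, by = 0.5)
  for (g in c(0.17, 1, 2)) {
    p <- gompertz_params(0.5, 1500, gamma = g, eff = 0.6, v0 = 80)
    v_untreated <- predict_volume(p, treatment_schedule(FALSE), t)
    ## non-decreasing everywhere; strictly increasing below the plateau
    ## (gamma < 1 reaches v_max in finite time, gamma >= 1 never does)
    expect_true(all(diff(v_untreated) >= 0))
    below <- v_untreated < 1500 * (1 - 1e-9)
    expect_true(all(diff(v_untreated[below]) > 0))
    if (g >= 1) expect_true(all(below))
    expect_true(all(v_untreated >= 80 - 1e-9 & v_untreated <= 1500 + 1e-9))
    v_treated <- predict_volume(p, treatment_schedule(TRUE, start_time = 7), t)
    late <- t > 7 & below
    expect_true(all(v_treated[late] < v_untreated[late]))
    expect_true(all(v_treated <= v_untreated + 1e-9))
    expect_equal(v_treated[t <= 7], v_untreated[t <= 7])
  }
})

test_that("time/rate rescaling leaves the trajectory invariant", {
  t <- seq(0, 30, by = 1.5)
  for (cc in c(0.5, 2, 4)) {
    p1 <- gompertz_params(0.64, 1620, gamma = 0.17, v0 = 80)
    p2 <- gompertz_params(0.64 / cc, 1620, gamma = 0.17, v0 = 80)
    expect_equal(predict_volume(p1, times = t),
                 predict_volume(p2, times = t * cc), tolerance = 1e-12)
  }
})

test_that("shrinkage mode (eff > 1) produces decreasing volumes", {
  p <- gompertz_params(0.5, 1500, gamma = 0.17, eff = 1.5, v0 = 200)
  s <- treatment_schedule(TRUE, start_time = 0)
  v <- predict_volume(p, s, times = c(0, 5, 10), shrinkage = TRUE)
  expect_true(all(diff(v) < 0))
  expect_error(predict_volume(p, s, times = c(0, 5)), "shrinkage")
})
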