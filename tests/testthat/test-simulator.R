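test_that("individual parameter sampling matches the population law", {
  pop <- population_params()
  ## degenerate: zero spread reproduces the means exactly
  pop0 <- population_params(omega_k = 0, omega_vmax = 0, omega_eff = 0)
  ps <- sample_individual_params(pop0, "A438079", 5, seed = 1)
  expect_true(all(vapply(ps, `[[`, 1, "k_growth") == 0.64))
  expect_true(all(vapply(ps, `[[`, 1, "eff") == 0.52))
  ## vehicle animals carry no treatment effect
  pv <- sample_individual_params(pop, "vehicle", 5, seed = 1)
  expect_true(all(vapply(pv, `[[`, 1, "eff") == 0))
  ## determinism
  a <- sample_individual_params(pop, "AZ10606120", 10, seed = 42)
  b <- sample_individual_params(pop, "AZ10606120", 10, seed = 42)
  expect_identical(a, b)
  expect_error(sample_individual_params(pop, c("x", "y"), 3), "arm")
})

test_that("log-scale spread of sampled k_growth matches omega_k", {
  pop <- population_params()
  ps <- sample_individual_params(pop, "vehicle", 1e5, seed = 7)
  lk <- log(vapply(ps, `[[`, 1, "k_growth"))
  expect_equal(sd(lk), 0.39, tolerance = 0.01)
  expect_equal(mean(lk), log(0.64), tolerance = 0.01)
})

test_that("simulated cohorts respect the study design", {
  des <- study_design(n_per_arm = 10)
  pop <- population_params()
  sim <- simulate_cohort(des, pop, seed = 3)
  g <- sim$growth
  expect_equal(sort(unique(g$arm)), sort(des$arms))
  expect_equal(nrow(g), 3 * 10 * length(des$obs_times))
  expect_true(all(g$volume_mm3 > 0))
  expect_false(anyDuplicated(g[, c("animal_id", "time_day")]) > 0)
  ## enrollment: first observation near the 80 mm^3 threshold
  first <- g[g$time_day == 0, ]
  resid_sd <- sqrt((0.15 * 80)^2 + 5^2)
  expect_true(all(first$volume_mm3 >= 80 - 3 * sqrt(2) * resid_sd))
  ## survival times positive, events only when the endpoint is reachable
  expect_true(all(sim$survival$time_day > 0))
  expect_true(all(sim$survival$event %in% 0:1))
  ## censoring happens only at the study end
  cens <- sim$survival$event == 0
  expect_true(all(sim$survival$time_day[cens] == des$study_end))
  expect_true(all(sim$survival$event[sim$survival$time_day <
                                       des$study_end] == 1))
})

test_that("empty and noiseless designs behave as limits", {
  des0 <- study_design(n_per_arm = 0)
  sim0 <- simulate_cohort(des0, population_params(), seed = 1)
  expect_null(sim0$growth)
  ## noiseless, zero-spread vehicle cohort equals the mean model curve
  popd <- population_params(omega_k = 0, omega_vmax = 0, omega_eff = 0,
                            sigma_prop = 0, sigma_add = 0)
  desv <- study_design(arms = "vehicle", n_per_arm = 3)
  simd <- simulate_cohort(desv, popd, seed = 2)
  p <- gompertz_params(0.64, 1620, gamma = 0.17, v0 = 80)
  expected <- predict_volume(p, times = desv$obs_times)
  for (id in unique(simd$growth$animal_id)) {
    expect_equal(simd$growth$volume_mm3[simd$growth$animal_id == id],
                 expected, tolerance = 1e-10)
  }
})

test_that("stronger treatment effect lowers final volumes in treated arms", {
  finals <- vapply(c(0.2, 0.5, 0.8), function(em) {
    pop <- population_params(eff_mean = em)
    sim <- simulate_cohort(study_design(arms = c("vehicle", "A438079"),
                                        n_per_arm = 15), pop, seed = 11)
    g <- sim$growth
    mean(g$volume_mm3[g$arm == "A438079" & g$time_day == 28])
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("growth and survival tables round-trip through CSV", {
  sim <- small_cohort(seed = 5)
  gf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  write_growth_data(sim$growth, gf)
  back <- read_growth_data(gf)
  expect_equal(back$volume_mm3, sim$growth$volume_mm3, tolerance = 1e-12)
  expect_identical(back$animal_id, sim$growth$animal_id)
  write_survival_data(sim$survival, sf)
  sback <- read_survival_data(sf)
  expect_equal(sback$time_day, sim$survival$time_day, tolerance = 1e-12)
  expect_identical(sback$event, sim$survival$event)
})

test_that("growth data validation catches schema violations", {
  g <- small_cohort(seed = 6)$growth
  expect_silent(validate_growth_data(g))
  bad <- g; bad$volume_mm3[3] <- -2
  expect_error(validate_growth_data(bad), "invalid growth rows")
  dup <- rbind(g, g[1, ])
  expect_error(validate_growth_data(dup), "duplicated")
  expect_error(validate_growth_data(g[, 1:3]), "lacks columns")
  single <- g[g$animal_id == g$animal_id[1], ][1, ]
  expect_error(validate_growth_data(rbind(g, transform(single,
    animal_id = "lonely"))), "2 observations")
})

test_that("simulated dose-response hits the Hill anchors", {
  conc <- c(0.3, 1, 3, 4.3, 5, 10)
  dr <- simulate_dose_response(4.3, 1.5, conc, n_cells = 2, noise_sd = 0)
  hill <- function(c, n = 1.5, e = 4.3) c^n / (c^n + e^n)
  ## half-maximal before rescaling: r(ec50)/r(ref) = 0.5 / r(10)
  r_ec50 <- dr$response[dr$concentration_mM == 4.3][1]
  expect_equal(r_ec50, 0.5 / hill(10), tolerance = 1e-12)
  expect_equal(dr$response[dr$concentration_mM == 10][1], 1)
  expect_error(simulate_dose_response(4.3, 1.5, numeric(0)), "non-empty")
  a <- simulate_dose_response(4.3, 1.5, conc, 3, 0.05, seed = 9)
  b <- simulate_dose_response(4.3, 1.5, conc, 3, 0.05, seed = 9)
  expect_identical(a, b)
})
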