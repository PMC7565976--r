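## Fast, structurally-focused SAEM checks; statistical recovery at the
## study's printed values lives in test-acceptance.R.

test_that("near-noiseless, zero-IIV vehicle data is recovered within 1%", {
  pop0 <- population_params(omega_k = 0, omega_vmax = 0, omega_eff = 0,
                            sigma_prop = 0.002, sigma_add = 0.05)
  des0 <- study_design(arms = "vehicle", n_per_arm = 8,
                       obs_times = seq(0, 14, by = 1))
  sim0 <- simulate_cohort(des0, pop0, seed = 5)
  fit0 <- suppressWarnings(
    saem_fit(sim0$growth, saem_control(n_burnin = 300, n_iter = 200,
                                       seed = 6)))
  expect_equal(fit0$estimates$k_growth_mean, 0.64, tolerance = 0.01)
  expect_equal(fit0$estimates$v_max_mean, 1620, tolerance = 0.01)
  expect_equal(fit0$estimates$gamma, 0.17, tolerance = 0.05)
})

test_that("renaming animal ids leaves the fit unchanged", {
  g <- small_cohort(seed = 12, n = 5)$growth
  ctrl <- saem_control(n_burnin = 60, n_iter = 40, seed = 9)
  f1 <- suppressWarnings(saem_fit(g, ctrl))
  g2 <- g
  g2$animal_id <- paste0("mouse_", match(g$animal_id, unique(g$animal_id)))
  f2 <- suppressWarnings(saem_fit(g2, ctrl))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-12)
})

test_that("animal ordering only perturbs estimates at Monte-Carlo level", {
  pop <- population_params(omega_k = 0.2, omega_vmax = 0.2,
                           omega_eff = 0.25, sigma_prop = 0.05,
                           sigma_add = 1)
  des <- study_design(arms = c("vehicle", "A438079"), n_per_arm = 8,
                      obs_times = seq(0, 14, by = 2))
  g <- simulate_cohort(des, pop, seed = 14)$growth
  ctrl <- saem_control(n_burnin = 250, n_iter = 200, seed = 15)
  f1 <- suppressWarnings(saem_fit(g, ctrl))
  ord <- order(rev(match(g$animal_id, unique(g$animal_id))), g$time_day)
  f2 <- suppressWarnings(saem_fit(g[ord, ], ctrl))
  for (p in c("k_growth_mean", "v_max_mean", "eff_mean")) {
    expect_equal(f1$estimates[[p]], f2$estimates[[p]], tolerance = 0.1)
  }
})

test_that("an arm covariate on k_growth is estimated multiplicatively", {
  pop <- population_params(omega_k = 0.15, omega_vmax = 0.15,
                           sigma_prop = 0.05, sigma_add = 1)
  des <- study_design(arms = "vehicle", n_per_arm = 10,
                      obs_times = seq(0, 14, by = 1))
  slow <- population_params(k_growth_mean = 0.64 * 0.6, omega_k = 0.15,
                            omega_vmax = 0.15, sigma_prop = 0.05,
                            sigma_add = 1)
  g1 <- simulate_cohort(des, pop, seed = 31)$growth
  g2 <- simulate_cohort(des, slow, seed = 32)$growth
  g2$animal_id <- sub("vehicle", "slow", g2$animal_id)
  g2$arm <- "slowline"
  g <- rbind(g1, g2)
  fit <- suppressWarnings(saem_fit(g, saem_control(
    n_burnin = 300, n_iter = 200, seed = 33,
    untreated_arms = c("vehicle", "slowline"),
    covariate_model = list(k_growth = "slowline"))))
  expect_equal(fit$covariate_effects[["k_growth:slowline"]], 0.6,
               tolerance = 0.12)
})

test_that("input validation rejects unusable datasets and settings", {
  g <- small_cohort(seed = 1, n = 2)$growth
  one <- g[g$animal_id == g$animal_id[1], ]
  expect_error(saem_fit(one), ">= 2 animals")
  expect_error(saem_control(sa_exponent = 0.4), "sa_exponent")
  expect_error(saem_control(n_burnin = 0), "iteration counts")
  expect_error(saem_control(covariate_model = list(foo = "a")), "unknown")
  expect_error(
    suppressWarnings(saem_fit(g, saem_control(
      n_burnin = 5, n_iter = 5, seed = 1,
      covariate_model = list(k_growth = "no_such_arm")))),
    "unknown arm")
})

test_that("the SAEM trace stabilizes over the smoothing phase", {
  g <- small_cohort(seed = 18, n = 8)$growth
  fit <- suppressWarnings(
    saem_fit(g, saem_control(n_burnin = 250, n_iter = 200, seed = 19)))
  tail_tr <- utils::tail(fit$trace, 40) # last 20% of iterations
  for (p in c("k_growth_mean", "v_max_mean", "eff_mean")) {
    expect_lt(sd(tail_tr[[p]]) / mean(tail_tr[[p]]), 0.02)
  }
})
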