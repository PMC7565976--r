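## Build a fit object with prescribed population values on a given
## dataset, bypassing estimation — used to probe log_likelihood() and
## lrt() at known points.
fit_at <- function(g, pop, omega_small = NULL) {
  fit <- suppressWarnings(
    saem_fit(g, saem_control(n_burnin = 5, n_iter = 5, seed = 1,
                             init = pop)))
  fit$beta$k <- log(pop$k_growth_mean)
  fit$beta$vmax <- log(pop$v_max_mean)
  if (fit$has_eff) fit$beta$eff <- log(pop$eff_mean)
  fit$omega <- if (is.null(omega_small)) {
    c(pop$omega_k, pop$omega_vmax, pop$omega_eff)
  } else rep(omega_small, 3)
  fit$estimates <- pop
  fit
}

test_that("vanishing IIV reduces the marginal likelihood to the residual one", {
  pop <- population_params(sigma_prop = 0.1, sigma_add = 2)
  des <- study_design(arms = "vehicle", n_per_arm = 3)
  g <- simulate_cohort(des, pop, seed = 40)$growth
  fit <- fit_at(g, pop, omega_small = 1e-3)
  fit <- log_likelihood(fit, n_samples = 2000, seed = 41)
  ## analytic limit: residual log-density at the population parameters,
  ## trajectories anchored at each animal's first observation
  ll_direct <- 0
  for (id in unique(g$animal_id)) {
    gi <- g[g$animal_id == id, ]
    p <- gompertz_params(pop$k_growth_mean, pop$v_max_mean,
                         gamma = pop$gamma, v0 = gi$volume_mm3[1])
    f <- predict_volume(p, times = gi$time_day)[-1]
    sd <- sqrt(pop$sigma_add^2 + (pop$sigma_prop * f)^2)
    ll_direct <- ll_direct + sum(dnorm(gi$volume_mm3[-1], f, sd, log = TRUE))
  }
  ## the O(omega^2) correction to the point-mass limit stays tiny
  expect_equal(fit$loglik, ll_direct, tolerance = 5e-4)
})

test_that("relabeling animals leaves the log-likelihood unchanged", {
  pop <- population_params()
  g <- small_cohort(seed = 44, n = 4)$growth
  fit <- fit_at(g, pop)
  f1 <- log_likelihood(fit, n_samples = 300, seed = 45)
  g2 <- g
  g2$animal_id <- paste0("relab_", match(g$animal_id, unique(g$animal_id)))
  fit2 <- fit_at(g2, pop)
  fit2$phi <- fit$phi
  f2 <- log_likelihood(fit2, n_samples = 300, seed = 45)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("SAEM estimates beat perturbed initial values in likelihood", {
  pop <- population_params(omega_k = 0.2, omega_vmax = 0.2,
                           omega_eff = 0.25, sigma_prop = 0.08,
                           sigma_add = 2)
  des <- study_design(arms = c("vehicle", "A438079"), n_per_arm = 10,
                      obs_times = seq(0, 14, by = 1))
  g <- simulate_cohort(des, pop, seed = 47)$growth
  fit <- suppressWarnings(saem_fit(g, saem_control(
    n_burnin = 300, n_iter = 200, seed = 48)))
  fit <- log_likelihood(fit, n_samples = 1000, seed = 49)
  perturbed <- population_params(
    k_growth_mean = pop$k_growth_mean * 1.7,
    v_max_mean = pop$v_max_mean * 0.5,
    eff_mean = pop$eff_mean * 2, omega_k = 0.5, omega_vmax = 0.5,
    omega_eff = 0.5, gamma = 0.6, sigma_prop = 0.2, sigma_add = 5)
  fit_pert <- fit_at(g, perturbed)
  fit_pert <- log_likelihood(fit_pert, n_samples = 1000, seed = 49)
  expect_gt(fit$loglik, fit_pert$loglik)
})

test_that("lrt wires the chi-square reference correctly", {
  g <- small_cohort(seed = 50, n = 3)$growth
  pop <- population_params()
  base <- fit_at(g, pop)
  f0 <- base; f0$loglik <- -100; f0$loglik_se <- 0.01
  f1 <- base; f1$loglik <- -100; f1$loglik_se <- 0.01
  f1$n_model_params <- f0$n_model_params + 1L
  eq <- lrt(f0, f1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$df, 1L)
  ## 3.841 on 1 df sits at the 5% point
  f2 <- f1; f2$loglik <- -100 + 3.841 / 2
  expect_equal(lrt(f0, f2)$p_value, 0.05, tolerance = 1e-3)
  ## a markedly negative statistic is clamped with a warning
  f3 <- f1; f3$loglik <- -103
  expect_warning(res <- lrt(f0, f3), "clamped")
  expect_equal(res$statistic, 0)
  expect_error(lrt(f0, f0), "at least one parameter")
})
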