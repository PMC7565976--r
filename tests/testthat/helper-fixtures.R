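## Shared fixtures, built in code at test time.

## Printed population values of the emulated in vivo study.
study_pop <- function(...) population_params(...)

## Small, fast cohort for structural tests.
small_cohort <- function(seed = 1, n = 4, arms = c("vehicle", "A438079")) {
  simulate_cohort(
    study_design(arms = arms, n_per_arm = n),
    population_params(), seed = seed)
}

## Closed-form classic Gompertz (gamma = 1), the oracle for the integrator.
gompertz_closed_form <- function(t, v0, v_max, k) {
  v_max * (v0 / v_max)^exp(-k * t)
}
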