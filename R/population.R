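#' Population parameters of the Gompertz growth model
#'
#' Population-level description used both to simulate cohorts and as the
#' estimand of the mixed-effects fit. Individual `k_growth`, `v_max` and
#' (for treated animals) `eff` are log-normally distributed:
#' `log X ~ Normal(log mean, omega^2)`, so each `*_mean` is the population
#' typical value (the log-normal median) and each `omega` is the standard
#' deviation of the log-scale random effect — the inter-individual
#' variability usually quoted as a percentage (`omega = 0.39` is "39%").
#' `gamma` is a fixed effect shared by all animals. Residual error on an
#' observed volume `y` with model prediction `f` is combined
#' proportional + additive: `y = f + e`, `sd(e) = sqrt(sigma_add^2 +
#' (sigma_prop * f)^2)`.
#'
#' Defaults are the population values estimated in a syngeneic mammary
#' (4T1) study of P2X7-antagonist treatment: `k_growth = 0.64/day` (39%),
#' `v_max = 1620 mm^3` (64%), `eff = 0.52` (82%), `gamma = 0.17`.
#'
#' @param k_growth_mean typical growth rate constant (1/day).
#' @param omega_k sd of `log(k_growth)` across animals (>= 0).
#' @param v_max_mean typical plateau volume (mm^3).
#' @param omega_vmax sd of `log(v_max)` (>= 0).
#' @param eff_mean typical treatment effect (treated arms only).
#' @param omega_eff sd of `log(eff)` (>= 0).
#' @param gamma power coefficient (> 0), no inter-individual variability.
#' @param sigma_prop proportional residual sd (fraction, >= 0).
#' @param sigma_add additive residual sd (mm^3, >= 0).
#' @return an object of class `"population_params"`.
#' @export
population_params <- function(k_growth_mean = 0.64, omega_k = 0.39,
                              v_max_mean = 1620, omega_vmax = 0.64,
                              eff_mean = 0.52, omega_eff = 0.82,
                              gamma = 0.17,
                              sigma_prop = 0.15, sigma_add = 5) {
  vals <- c(k_growth_mean = k_growth_mean, v_max_mean = v_max_mean,
            eff_mean = eff_mean, gamma = gamma)
  if (any(vals <= 0)) {
    stop("population means and gamma must be > 0: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  oms <- c(omega_k = omega_k, omega_vmax = omega_vmax, omega_eff = omega_eff,
           sigma_prop = sigma_prop, sigma_add = sigma_add)
  if (any(oms < 0)) {
    stop("variability terms must be >= 0: ",
         paste(names(oms)[oms < 0], collapse = ", "))
  }
  structure(list(k_growth_mean = k_growth_mean, omega_k = omega_k,
                 v_max_mean = v_max_mean, omega_vmax = omega_vmax,
                 eff_mean = eff_mean, omega_eff = omega_eff,
                 gamma = gamma, sigma_prop = sigma_prop,
                 sigma_add = sigma_add),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population Gompertz parameters (typical value, IIV sd of log):\n")
  cat(sprintf("  k_growth : %.4g /day   (omega %.3g)\n", x$k_growth_mean, x$omega_k))
  cat(sprintf("  v_max    : %.4g mm^3   (omega %.3g)\n", x$v_max_mean, x$omega_vmax))
  cat(sprintf("  eff      : %.4g        (omega %.3g)\n", x$eff_mean, x$omega_eff))
  cat(sprintf("  gamma    : %.4g        (fixed effect)\n", x$gamma))
  cat(sprintf("  residual : sigma_prop %.3g, sigma_add %.3g mm^3\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Study design of a simulated tumour-growth experiment
#'
#' Emulates the in vivo design in which animals are enrolled and dosing
#' starts once the tumour reaches a threshold volume (80 mm^3 by default),
#' volumes are caliper-measured twice a week, and animals reaching a humane
#' endpoint volume are removed (the survival event).
#'
#' @param arms character vector of arm labels; `"vehicle"` is the untreated
#'   reference arm, any other label is a treated arm.
#' @param n_per_arm animals per arm (>= 0).
#' @param enrollment_threshold volume triggering enrollment/treatment start
#'   (mm^3).
#' @param obs_times observation days relative to treatment start; default
#'   twice weekly over 28 days.
#' @param endpoint_volume humane-endpoint volume defining the survival
#'   event (mm^3).
#' @param study_end last follow-up day; animals not reaching the endpoint
#'   are censored here.
#' @param dosing_interval days between doses (metadata).
#' @return an object of class `"study_design"`.
#' @export
study_design <- function(arms = c("vehicle", "A438079", "AZ10606120"),
                         n_per_arm = 10,
                         enrollment_threshold = 80,
                         obs_times = seq(0, 28, by = 3.5),
                         endpoint_volume = 1500,
                         study_end = 60,
                         dosing_interval = 2) {
  if (length(arms) < 1 || anyDuplicated(arms)) {
    stop("arms must be a non-empty set of unique labels")
  }
  if (n_per_arm < 0) stop("n_per_arm must be >= 0")
  if (enrollment_threshold <= 0 || endpoint_volume <= 0) {
    stop("volume thresholds must be > 0")
  }
  if (length(obs_times) < 1 || any(obs_times < 0) || is.unsorted(obs_times)) {
    stop("obs_times must be sorted and non-negative")
  }
  if (study_end <= 0) stop("study_end must be > 0")
  structure(list(arms = as.character(arms), n_per_arm = as.integer(n_per_arm),
                 enrollment_threshold = enrollment_threshold,
                 obs_times = obs_times, endpoint_volume = endpoint_volume,
                 study_end = study_end, dosing_interval = dosing_interval),
            class = "study_design")
}

## Run code with a private RNG stream; leaves the caller's stream intact.
## seed = NULL means: use (and advance) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
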