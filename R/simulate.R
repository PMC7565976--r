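#' Draw individual Gompertz parameters from a population law
#'
#' Samples per-animal `k_growth`, `v_max` and — for treated arms — `eff`
#' from log-normal distributions: `log X ~ Normal(log mean, omega^2)`.
#' `gamma` is copied unchanged (no inter-individual variability). Animals
#' in the `"vehicle"` arm get `eff = 0`.
#'
#' @param pop a [population_params()] object.
#' @param arm arm label; `"vehicle"` is untreated, any other label treated.
#' @param n number of animals (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @param v0 initial volume assigned to every animal (mm^3); individual
#'   initial volumes are normally set later by the cohort simulator.
#' @return a list of [gompertz_params()] objects of length `n`.
#' @export
sample_individual_params <- function(pop, arm, n, seed = NULL, v0 = 80) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.character(arm) || length(arm) != 1L || !nzchar(arm)) {
    stop("unknown arm label: must be a single non-empty string")
  }
  if (n < 0) stop("n must be >= 0")
  treated <- arm != "vehicle"
  with_seed(seed, {
    k <- stats::rlnorm(n, log(pop$k_growth_mean), pop$omega_k)
    vm <- stats::rlnorm(n, log(pop$v_max_mean), pop$omega_vmax)
    ef <- if (treated) {
      stats::rlnorm(n, log(pop$eff_mean), pop$omega_eff)
    } else {
      rep(0, n)
    }
    lapply(seq_len(n), function(i) {
      gompertz_params(k_growth = k[i], v_max = max(vm[i], v0),
                      gamma = pop$gamma, eff = ef[i],
                      v0 = min(v0, vm[i]))
    })
  })
}

## First time at which the noise-free trajectory V(t) crosses `target`,
## or Inf when v_max <= target (never crossed). Closed-form inverse of the
## Gompertz solution; k_eff constant from t = 0 (treatment starts at the
## time origin in this design).
.gomp_crossing_time <- function(v0, v_max, gamma, k_eff, target) {
  if (k_eff <= 0 || v_max <= target || v0 >= target) {
    return(if (v0 >= target && v0 > 0) 0 else Inf)
  }
  u0 <- log(v_max / v0)
  ue <- log(v_max / target)
  if (gamma == 1) {
    log(u0 / ue) / k_eff
  } else {
    e <- 1 - gamma
    (u0^e - ue^e) / (k_eff * e)
  }
}

#' Simulate a longitudinal tumour-growth cohort
#'
#' For each animal: individual parameters are drawn from the population
#' law, the true initial volume is the enrollment threshold perturbed by
#' one realization of the measurement-error model, the noise-free
#' trajectory is computed with the generalized Gompertz law (treatment
#' active from day 0 in treated arms), and observations at the design's
#' `obs_times` add combined proportional + additive residual error
#' (floored at 1 mm^3). The survival time is the first time the noise-free
#' trajectory crosses `endpoint_volume` (event = 1), otherwise the animal
#' is censored at `study_end` (event = 0).
#'
#' @param design a [study_design()] object.
#' @param pop a [population_params()] object.
#' @param seed optional integer seed.
#' @return a list with components `growth` (data frame: `animal_id`, `arm`,
#'   `time_day`, `volume_mm3`), `survival` (data frame: `animal_id`,
#'   `group`, `time_day`, `event`) and `params` (per-animal true
#'   parameters, for simulation studies).
#' @export
simulate_cohort <- function(design, pop, seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(pop, "population_params"))
  with_seed(seed, {
    growth <- list(); surv <- list(); truth <- list()
    id <- 0L
    for (arm in design$arms) {
      treated <- arm != "vehicle"
      n <- design$n_per_arm
      if (n == 0L) next
      k <- stats::rlnorm(n, log(pop$k_growth_mean), pop$omega_k)
      vm <- stats::rlnorm(n, log(pop$v_max_mean), pop$omega_vmax)
      ef <- if (treated) stats::rlnorm(n, log(pop$eff_mean), pop$omega_eff)
            else rep(0, n)
      for (i in seq_len(n)) {
        id <- id + 1L
        aid <- sprintf("%s_%02d", arm, i)
        ## true initial volume: threshold perturbed by measurement error
        thr <- design$enrollment_threshold
        v0 <- thr * (1 + stats::rnorm(1, 0, pop$sigma_prop)) +
          stats::rnorm(1, 0, pop$sigma_add)
        v0 <- max(v0, 1)
        vmax_i <- max(vm[i], v0 * (1 + 1e-6))
        keff <- k[i] * (1 - ef[i]) # treated from t = 0; vehicle has ef = 0
        u0 <- log(vmax_i / v0)
        vtrue <- vmax_i * exp(-.gomp_u(u0, keff, pop$gamma,
                                       design$obs_times))
        yobs <- vtrue * (1 + stats::rnorm(length(vtrue), 0, pop$sigma_prop)) +
          stats::rnorm(length(vtrue), 0, pop$sigma_add)
        yobs <- pmax(yobs, 1)
        growth[[id]] <- data.frame(animal_id = aid, arm = arm,
                                   time_day = design$obs_times,
                                   volume_mm3 = yobs)
        tcross <- .gomp_crossing_time(v0, vmax_i, pop$gamma, keff,
                                      design$endpoint_volume)
        surv[[id]] <- data.frame(
          animal_id = aid, group = arm,
          time_day = min(tcross, design$study_end),
          event = as.integer(tcross <= design$study_end))
        truth[[id]] <- data.frame(animal_id = aid, arm = arm,
                                  k_growth = k[i], v_max = vmax_i,
                                  eff = ef[i], gamma = pop$gamma, v0 = v0)
      }
    }
    list(growth = do.call(rbind, growth),
         survival = do.call(rbind, surv),
         params = do.call(rbind, truth))
  })
}

#' Simulate normalized concentration-response measurements
#'
#' Generates per-cell replicates of a Hill-law response
#' \eqn{r(c) = c^n / (c^n + EC_{50}^n)}, rescaled so that the reference
#' (largest) concentration maps to 1 — mimicking currents expressed as a
#' ratio of the response at the top concentration — with additive Gaussian
#' noise per cell and concentration.
#'
#' @param ec50 half-maximal concentration (mM).
#' @param hill_n Hill coefficient (> 0).
#' @param concentrations vector of tested concentrations (mM, > 0); the
#'   maximum is the normalization reference.
#' @param n_cells number of replicate cells.
#' @param noise_sd sd of additive noise on the normalized response.
#' @param seed optional integer seed.
#' @return data frame with columns `concentration_mM`, `cell_id`,
#'   `response`.
#' @export
simulate_dose_response <- function(ec50, hill_n, concentrations,
                                   n_cells = 6, noise_sd = 0.05,
                                   seed = NULL) {
  if (length(concentrations) == 0) stop("concentration list must be non-empty")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (ec50 <= 0 || hill_n <= 0) stop("ec50 and hill_n must be > 0")
  cref <- max(concentrations)
  hill <- function(c) c^hill_n / (c^hill_n + ec50^hill_n)
  r <- hill(concentrations) / hill(cref)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_cells), function(cell) {
      data.frame(concentration_mM = concentrations,
                 cell_id = sprintf("cell_%02d", cell),
                 response = r + stats::rnorm(length(r), 0, noise_sd))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Read / write the package's tabular data formats
#'
#' Plain-CSV serialization of the longitudinal growth table
#' (`animal_id, arm, time_day, volume_mm3`), the survival table
#' (`animal_id, group, time_day, event`) and the dose-response table
#' (`concentration_mM, cell_id, response`). Reading validates the schema
#' and basic invariants and fails with an informative error listing the
#' offending rows.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_*` return the validated data frame; `write_*` return
#'   `path` invisibly.
#' @name growth_io
NULL

#' @rdname growth_io
#' @export
write_growth_data <- function(x, path) {
  utils::write.csv(x[, c("animal_id", "arm", "time_day", "volume_mm3")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname growth_io
#' @export
read_growth_data <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_growth_data(x)
}

#' @rdname growth_io
#' @export
validate_growth_data <- function(x) {
  need <- c("animal_id", "arm", "time_day", "volume_mm3")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("growth data lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(x$volume_mm3) | x$volume_mm3 <= 0 |
                 !is.finite(x$time_day) | x$time_day < 0)
  if (length(bad)) {
    stop("invalid growth rows (non-positive volume or bad time): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (anyDuplicated(x[, c("animal_id", "time_day")])) {
    stop("duplicated (animal_id, time_day) pairs")
  }
  nobs <- table(x$animal_id)
  if (any(nobs < 2)) {
    stop("every animal needs >= 2 observations; offending: ",
         paste(names(nobs)[nobs < 2], collapse = ", "))
  }
  x
}

#' @rdname growth_io
#' @export
write_survival_data <- function(x, path) {
  utils::write.csv(x[, c("animal_id", "group", "time_day", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname growth_io
#' @export
read_survival_data <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "time_day", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("survival data lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$time_day <= 0)) stop("survival times must be > 0")
  if (!all(x$event %in% c(0, 1))) stop("event flags must be 0/1")
  x
}
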