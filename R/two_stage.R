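#' Two-stage (per-animal) fit of the Gompertz population model
#'
#' Naive-pooling oracle and default SAEM initializer: every animal is fit
#' individually by least squares on the log scale (log residuals
#' approximate proportional error), with the power coefficient `gamma`
#' profiled globally over all animals; population typical values are then
#' the exponentials of the mean log parameters and the `omega`s the
#' standard deviations of the logs.
#'
#' Treated animals only identify their *effective* rate
#' `k_eff = k_growth * (1 - eff)`; the treatment effect is recovered by
#' contrast with the vehicle arm: `eff_i = 1 - k_eff_i / k_typ(vehicle)`.
#' Animals whose contrast gives `eff_i <= 0` are dropped from the `eff`
#' summary with a warning. With no vehicle animals the rate/effect split
#' is unidentifiable and `eff` is reported as `NA`.
#'
#' @param data growth data frame or CSV path (see [saem_fit()]).
#' @param min_obs minimum observations per animal (animals below are
#'   excluded with a warning; >= 4 recommended for a 2-parameter fit plus
#'   anchor).
#' @param gamma_interval search interval for the global `gamma` profile.
#' @param untreated_arms arm labels carrying no treatment effect.
#' @param quiet suppress warnings about excluded animals?
#' @return a [population_params()] object with an `"individual"` attribute
#'   holding the per-animal estimates.
#' @export
two_stage_fit <- function(data, min_obs = 4, gamma_interval = c(0.02, 3),
                          untreated_arms = "vehicle", quiet = FALSE) {
  if (is.character(data)) data <- read_growth_data(data)
  prep <- .prep_growth(data, min_animals = 1,
                       untreated_arms = untreated_arms)
  keep <- which(prep$n_obs + 1L >= min_obs)
  if (!length(keep)) stop("all animals excluded: too few observations")
  if (length(keep) < prep$n && !quiet) {
    warning("excluding ", prep$n - length(keep),
            " animal(s) with fewer than ", min_obs, " observations")
  }

  ## per-animal log-scale SSE for given gamma; returns fit list
  vmax_cap <- exp(prep$log_vmax_hi)
  fit_one <- function(i, gamma) {
    rows <- prep$row_animal == i
    t <- prep$t[rows]; y <- prep$y[rows]; v0 <- prep$v0[i]
    obj <- function(par) {
      keff <- par[1]; vmax <- exp(par[2])
      if (vmax <= v0 || vmax > vmax_cap || abs(keff) > 100) return(1e10)
      f <- vmax * exp(-.gomp_u(log(vmax / v0), keff, gamma, t))
      sum((log(y) - log(pmax(f, 1e-12)))^2)
    }
    ## starting values: slope of early log-volumes, plateau above max
    k0 <- max((log(y[1]) - log(v0)) / max(t[1], 0.5), 0.01)
    start <- c(k0, log(max(max(y) * 1.3, v0 * 2)))
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    list(keff = o2$par[1], vmax = exp(o2$par[2]), sse = o2$value,
         nres = length(y), conv = is.finite(o2$value) && o2$value < 1e9)
  }

  prof <- function(gamma) {
    sum(vapply(keep, function(i) fit_one(i, gamma)$sse, numeric(1)))
  }
  gamma_hat <- stats::optimize(prof, gamma_interval, tol = 1e-3)$minimum

  fits <- lapply(keep, fit_one, gamma = gamma_hat)
  ok <- vapply(fits, `[[`, logical(1), "conv") &
    vapply(fits, `[[`, numeric(1), "keff") > 0
  if (!any(ok)) stop("all per-animal fits failed")
  if (any(!ok) && !quiet) {
    warning("excluding ", sum(!ok), " animal(s) with degenerate fits")
  }
  keep <- keep[ok]; fits <- fits[ok]

  keff <- vapply(fits, `[[`, numeric(1), "keff")
  vmax <- vapply(fits, `[[`, numeric(1), "vmax")
  treated <- prep$treated[keep]

  ind <- data.frame(animal_id = prep$ids[keep], arm = prep$arm[keep],
                    k_eff = keff, v_max = vmax)

  lv <- log(vmax)
  v_typ <- exp(mean(lv))
  om_v <- if (length(lv) > 1) stats::sd(lv) else 0

  if (any(!treated)) {
    lk <- log(keff[!treated])
    k_typ <- exp(mean(lk))
    om_k <- if (sum(!treated) > 1) stats::sd(lk) else 0
  } else {
    lk <- log(keff)
    k_typ <- exp(mean(lk))
    om_k <- if (length(lk) > 1) stats::sd(lk) else 0
  }

  eff_typ <- NA_real_; om_e <- NA_real_
  if (any(treated) && any(!treated)) {
    eff_i <- 1 - keff[treated] / k_typ
    pos <- eff_i > 0
    if (any(!pos) && !quiet) {
      warning(sum(!pos), " treated animal(s) with non-positive apparent ",
              "effect dropped from the eff summary")
    }
    if (any(pos)) {
      le <- log(eff_i[pos])
      eff_typ <- exp(mean(le))
      om_e <- if (sum(pos) > 1) stats::sd(le) else 0
    }
  }

  ## residual scale from pooled log residuals
  resid2 <- unlist(lapply(seq_along(fits), function(j) {
    fits[[j]]$sse / max(fits[[j]]$nres, 1)
  }))
  sig_p <- sqrt(stats::median(resid2))

  out <- population_params(
    k_growth_mean = k_typ, omega_k = om_k,
    v_max_mean = v_typ, omega_vmax = om_v,
    eff_mean = if (is.na(eff_typ)) 1e-12 else eff_typ,
    omega_eff = if (is.na(om_e)) 0 else om_e,
    gamma = gamma_hat,
    sigma_prop = max(sig_p, 1e-4), sigma_add = 1)
  if (is.na(eff_typ)) out$eff_mean <- NA_real_
  if (is.na(om_e)) out$omega_eff <- NA_real_
  attr(out, "individual") <- ind
  out
}
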