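## log-sum-exp
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Observed-data log-likelihood by importance sampling
#'
#' Estimates the marginal (observed-data) log-likelihood of a fitted
#' population model by integrating the random effects out animal by
#' animal: the proposal is a multivariate normal centred on each animal's
#' conditional mode with covariance from the curvature there (inflated by
#' 1.5 for heavier tails), and the per-animal integral is averaged over
#' `n_samples` draws. A Monte-Carlo standard error is reported.
#'
#' @param fit a [saem_fit()] object.
#' @param n_samples importance-sampling draws per animal.
#' @param seed integer seed.
#' @return `fit`, with `loglik` and `loglik_se` filled in.
#' @export
log_likelihood <- function(fit, n_samples = 1000, seed = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  if (n_samples < 50) stop("n_samples too small for a stable estimate")
  prep <- .prep_growth(fit$data,
                       untreated_arms = fit$control$untreated_arms %||%
                         "vehicle")
  blocks <- .build_blocks(prep, fit$control$covariate_model)
  mu <- .block_mu(prep, blocks, fit$beta)
  omega <- fit$omega
  est <- fit$estimates
  gamma <- est$gamma; sig_add <- est$sigma_add; sig_prop <- est$sigma_prop

  ## per-animal observation log-likelihood for a matrix of phi draws
  ll_obs_one <- function(i, phim) {
    rows <- prep$row_animal == i
    t <- prep$t[rows]; y <- prep$y[rows]; v0 <- prep$v0[i]
    M <- nrow(phim); nj <- length(t)
    k <- exp(phim[, 1L]); vmax <- exp(phim[, 2L])
    eff <- if (prep$treated[i]) exp(phim[, 3L]) else rep(0, M)
    keff <- k * (1 - eff)
    bad <- vmax <= v0
    vmax_s <- pmax(vmax, v0 * (1 + 1e-12))
    u0 <- log(vmax_s / v0)
    u <- .gomp_u(rep(u0, each = nj), rep(keff, each = nj), gamma,
                 rep(t, times = M))
    f <- rep(vmax_s, each = nj) * exp(-u)
    sd <- sqrt(sig_add^2 + (sig_prop * f)^2)
    llr <- stats::dnorm(rep(y, times = M), f, sd, log = TRUE)
    ll <- colSums(matrix(llr, nrow = nj))
    ll[bad] <- -Inf
    ll
  }

  with_seed(seed, {
    total <- 0; var_tot <- 0
    for (i in seq_len(prep$n)) {
      d <- if (prep$treated[i]) 3L else 2L
      mu_i <- mu[i, 1:d]; om_i <- omega[1:d]
      ## conditional mode
      negpost <- function(ph) {
        phim <- matrix(c(ph, rep(0, 3L - d)), 1L)
        -(ll_obs_one(i, phim) +
            sum(stats::dnorm(ph, mu_i, om_i, log = TRUE)))
      }
      opt <- stats::optim(fit$phi[i, 1:d], negpost, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-9))
      mode_i <- opt$par
      H <- tryCatch(stats::optimHess(mode_i, negpost),
                    error = function(e) NULL)
      cov_q <- NULL
      if (!is.null(H)) {
        ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
        if (all(ev > 1e-8)) cov_q <- 1.5 * solve(H)
      }
      if (is.null(cov_q)) cov_q <- diag((om_i / 2)^2, d)
      ch <- chol(cov_q)
      z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
      draws <- sweep(z %*% ch, 2L, mode_i, "+")
      ## proposal log-density
      rt <- backsolve(ch, t(sweep(draws, 2L, mode_i)), transpose = TRUE)
      lq <- -0.5 * colSums(rt^2) - sum(log(diag(ch))) -
        0.5 * d * log(2 * pi)
      phim <- cbind(draws, matrix(0, n_samples, 3L - d))
      lp <- ll_obs_one(i, phim)
      for (j in 1:d) {
        lp <- lp + stats::dnorm(draws[, j], mu_i[j], om_i[j], log = TRUE)
      }
      lw <- lp - lq
      if (!any(is.finite(lw))) {
        stop("degenerate importance-sampling proposal for animal ",
             prep$ids[i], "; try a larger n_samples")
      }
      lw_max <- max(lw)
      w <- exp(lw - lw_max)
      total <- total + lw_max + log(mean(w))
      var_tot <- var_tot + stats::var(w) / (n_samples * mean(w)^2)
    }
    fit$loglik <- total
    fit$loglik_se <- sqrt(var_tot)
    fit
  })
}

#' Likelihood-ratio test between nested population models
#'
#' Compares two fitted models by twice the difference in observed-data
#' log-likelihoods against a chi-square reference with `df` degrees of
#' freedom (the number of added coefficients). The null model must be
#' nested in the alternative. A negative statistic beyond three combined
#' Monte-Carlo standard errors triggers a warning; negative values are
#' clamped to zero.
#'
#' @param fit_null,fit_alt [saem_fit()] objects; if their `loglik` is not
#'   yet computed, [log_likelihood()] is called with `n_samples`/`seed`.
#' @param df degrees of freedom; default is the difference in model
#'   parameter counts.
#' @param n_samples,seed passed to [log_likelihood()] when needed.
#' @return an object of class `"lrt_result"`: `statistic`, `df`,
#'   `p_value`, and the two log-likelihoods.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL, n_samples = 1000,
                seed = NULL) {
  stopifnot(inherits(fit_null, "saem_fit"), inherits(fit_alt, "saem_fit"))
  if (!is.finite(fit_null$loglik)) {
    fit_null <- log_likelihood(fit_null, n_samples, seed)
  }
  if (!is.finite(fit_alt$loglik)) {
    fit_alt <- log_likelihood(fit_alt, n_samples,
                              if (is.null(seed)) NULL else seed + 1L)
  }
  if (is.null(df)) df <- fit_alt$n_model_params - fit_null$n_model_params
  if (df < 1) stop("alternative model must add at least one parameter")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  se <- sqrt(fit_null$loglik_se^2 + fit_alt$loglik_se^2)
  if (stat < -3 * 2 * se) {
    warning("alternative log-likelihood below null beyond Monte-Carlo ",
            "error; statistic clamped to 0 (check convergence)")
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 loglik_null = fit_null$loglik,
                 loglik_alt = fit_alt$loglik,
                 loglik_se = se),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Simulation-based prediction intervals for tumour growth
#'
#' Simulates `n_sim` virtual animals per arm from a fitted (or known)
#' population law — individual parameters, enrollment-volume perturbation
#' and residual measurement error included — and returns pointwise
#' quantiles of the simulated observations over the design's observation
#' grid, e.g. the 90% prediction band (5th/95th percentiles) and the
#' median growth curve.
#'
#' @param fit a [saem_fit()] or [population_params()] object.
#' @param design a [study_design()]; arms and observation grid to predict.
#' @param quantiles probabilities of the pointwise quantiles.
#' @param n_sim virtual animals per arm; below 100 a warning about band
#'   instability is issued.
#' @param seed integer seed.
#' @return data frame: `arm`, `time_day`, one column `q<100p>` per
#'   requested quantile.
#' @export
predict_intervals <- function(fit, design = study_design(),
                              quantiles = c(0.05, 0.5, 0.95),
                              n_sim = 1000, seed = NULL) {
  if (inherits(fit, "saem_fit")) {
    pop <- fit$estimates
    cov_eff <- fit$covariate_effects
  } else if (inherits(fit, "population_params")) {
    pop <- fit
    cov_eff <- list()
  } else stop("fit must be a saem_fit or population_params object")
  if (n_sim < 100) warning("n_sim < 100: prediction band will be unstable")
  if (any(quantiles <= 0 | quantiles >= 1)) stop("quantiles must be in (0,1)")
  quantiles <- sort(quantiles)

  with_seed(seed, {
    out <- list()
    for (arm in design$arms) {
      treated <- arm != "vehicle"
      km <- pop$k_growth_mean *
        (cov_eff[[paste0("k_growth:", arm)]] %||% 1)
      vm <- pop$v_max_mean * (cov_eff[[paste0("v_max:", arm)]] %||% 1)
      em <- pop$eff_mean * (cov_eff[[paste0("eff:", arm)]] %||% 1)
      k <- stats::rlnorm(n_sim, log(km), pop$omega_k)
      vmax <- stats::rlnorm(n_sim, log(vm), pop$omega_vmax)
      eff <- if (treated) stats::rlnorm(n_sim, log(em), pop$omega_eff)
             else rep(0, n_sim)
      thr <- design$enrollment_threshold
      v0 <- pmax(thr * (1 + stats::rnorm(n_sim, 0, pop$sigma_prop)) +
                   stats::rnorm(n_sim, 0, pop$sigma_add), 1)
      vmax <- pmax(vmax, v0 * (1 + 1e-6))
      keff <- k * (1 - eff)
      tt <- design$obs_times
      nt <- length(tt)
      u <- .gomp_u(rep(log(vmax / v0), each = nt), rep(keff, each = nt),
                   pop$gamma, rep(tt, times = n_sim))
      f <- rep(vmax, each = nt) * exp(-u)
      y <- f * (1 + stats::rnorm(length(f), 0, pop$sigma_prop)) +
        stats::rnorm(length(f), 0, pop$sigma_add)
      y <- pmax(matrix(y, nrow = nt), 1)
      qm <- t(apply(y, 1L, stats::quantile, probs = quantiles,
                    names = FALSE))
      df <- data.frame(arm = arm, time_day = tt)
      for (j in seq_along(quantiles)) {
        df[[sprintf("q%g", 100 * quantiles[j])]] <- qm[, j]
      }
      out[[arm]] <- df
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
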