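#' Settings for the SAEM population fit
#'
#' Controls the stochastic approximation EM estimator: iteration counts for
#' the exploratory (burn-in) and smoothing phases, the number of
#' random-walk Metropolis sweeps per subject per iteration, the step-size
#' decay of the stochastic approximation, the covariate model, and the
#' initial population values.
#'
#' During burn-in the step size is 1 (pure stochastic EM) and decreases of
#' the variance components are damped (simulated-annealing style) to avoid
#' premature collapse of the random-effect distributions; in the smoothing
#' phase the step size is `(iter - n_burnin)^(-sa_exponent)`.
#'
#' @param n_burnin iterations of the exploratory phase (> 0).
#' @param n_iter iterations of the smoothing phase (> 0).
#' @param n_kernels random-walk Metropolis sweeps per iteration (>= 1); one
#'   independent proposal from the current population law is always added.
#' @param sa_exponent step-size decay exponent, in (0.5, 1].
#' @param init optional [population_params()] with initial values; default
#'   is a two-stage fit of the data.
#' @param covariate_model named list mapping `"k_growth"`, `"v_max"` or
#'   `"eff"` to character vectors of arm labels that receive their own
#'   multiplicative coefficient (reference: vehicle arm; for `eff`, the
#'   first treated arm).
#' @param seed integer seed for the stochastic estimation.
#' @param untreated_arms arm labels carrying no treatment effect
#'   (default `"vehicle"`); useful for sham/control comparisons.
#' @param verbose print progress every 50 iterations?
#' @return an object of class `"saem_control"`.
#' @export
saem_control <- function(n_burnin = 300, n_iter = 200, n_kernels = 2,
                         sa_exponent = 0.7, init = NULL,
                         covariate_model = list(), seed = NULL,
                         untreated_arms = "vehicle", verbose = FALSE) {
  if (n_burnin <= 0 || n_iter <= 0) stop("iteration counts must be > 0")
  if (n_kernels < 1) stop("n_kernels must be >= 1")
  if (sa_exponent <= 0.5 || sa_exponent > 1) {
    stop("sa_exponent must lie in (0.5, 1]")
  }
  bad <- setdiff(names(covariate_model), c("k_growth", "v_max", "eff"))
  if (length(bad)) stop("covariate_model: unknown parameters ",
                        paste(bad, collapse = ", "))
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 n_kernels = as.integer(n_kernels),
                 sa_exponent = sa_exponent, init = init,
                 covariate_model = covariate_model, seed = seed,
                 untreated_arms = untreated_arms,
                 verbose = isTRUE(verbose)),
            class = "saem_control")
}

## Restructure a long growth table for fitting. The earliest observation of
## each animal anchors the trajectory (fixes v0) and is excluded from the
## residual likelihood; remaining times are taken relative to the anchor.
.prep_growth <- function(data, min_animals = 2, untreated_arms = "vehicle") {
  data <- validate_growth_data(data)
  ids <- unique(data$animal_id)
  if (length(ids) < min_animals) {
    stop("need >= ", min_animals, " animals for a population fit")
  }
  ord <- order(match(data$animal_id, ids), data$time_day)
  data <- data[ord, ]
  first <- !duplicated(data$animal_id)
  anchor <- data[first, ]
  rest <- data[!first, ]
  arm <- anchor$arm
  names(arm) <- anchor$animal_id
  idx <- match(rest$animal_id, ids)
  t0 <- anchor$time_day[idx]
  list(ids = ids, n = length(ids),
       arm = unname(arm), treated = !(unname(arm) %in% untreated_arms),
       v0 = anchor$volume_mm3,
       row_animal = idx,
       t = rest$time_day - t0,
       y = rest$volume_mm3,
       n_obs = as.integer(table(factor(rest$animal_id, levels = ids))),
       ## identifiability bound: a plateau far above anything observed is
       ## indistinguishable from exponential growth (gamma -> 0 ridge)
       log_vmax_hi = log(50 * max(data$volume_mm3)),
       log_k_lo = log(1e-4), log_k_hi = log(100),
       log_eff_hi = log(100))
}

## Per-animal conditional log-likelihood of the observations given the
## individual parameters (columns of phi: log k, log vmax, log eff) and the
## residual/structural fixed effects. Returns a vector over animals.
.obs_loglik <- function(prep, phi, gamma, sig_add, sig_prop) {
  k <- exp(phi[, 1L])
  vmax <- exp(phi[, 2L])
  eff <- ifelse(prep$treated, exp(phi[, 3L]), 0)
  keff <- k * (1 - eff)
  bad <- vmax <= prep$v0 | phi[, 2L] > prep$log_vmax_hi |
    phi[, 1L] < prep$log_k_lo | phi[, 1L] > prep$log_k_hi |
    (prep$treated & phi[, 3L] > prep$log_eff_hi)
  u0 <- log(pmax(vmax, prep$v0 * (1 + 1e-12)) / prep$v0)
  ia <- prep$row_animal
  u <- .gomp_u(u0[ia], keff[ia], gamma, prep$t)
  f <- vmax[ia] * exp(-u)
  sd <- sqrt(sig_add^2 + (sig_prop * f)^2)
  ll_row <- stats::dnorm(prep$y, f, sd, log = TRUE)
  ll <- as.numeric(rowsum(ll_row, ia, reorder = TRUE))
  ll[bad] <- -Inf
  ll
}

## Row-level model predictions for the current phi (used by the residual /
## gamma profile updates).
.obs_pred <- function(prep, phi, gamma) {
  k <- exp(phi[, 1L])
  vmax <- exp(phi[, 2L])
  eff <- ifelse(prep$treated, exp(phi[, 3L]), 0)
  keff <- k * (1 - eff)
  u0 <- log(pmax(vmax / prep$v0, 1 + 1e-12))
  ia <- prep$row_animal
  vmax[ia] * exp(-.gomp_u(u0[ia], keff[ia], gamma, prep$t))
}

## Log-density of the random effects under the current population law.
## mu is the n x 3 matrix of per-animal means X beta; omega length 3.
.prior_loglik <- function(prep, phi, mu, omega) {
  ll <- stats::dnorm(phi[, 1L], mu[, 1L], omega[1L], log = TRUE) +
    stats::dnorm(phi[, 2L], mu[, 2L], omega[2L], log = TRUE)
  lle <- stats::dnorm(phi[, 3L], mu[, 3L], omega[3L], log = TRUE)
  ll + ifelse(prep$treated, lle, 0)
}

## Design matrices for the three log-scale parameter blocks.
## Each block: X (animals-in-block x q), rows (animal indices), labels.
.build_blocks <- function(prep, covariate_model) {
  arms <- unique(prep$arm)
  treated_arms <- setdiff(arms, "vehicle")
  blk <- function(param, rows, ref_label) {
    covs <- covariate_model[[param]]
    covs <- covs[covs %in% prep$arm[rows]]
    if (!is.null(covariate_model[[param]])) {
      unknown <- setdiff(covariate_model[[param]], arms)
      if (length(unknown)) {
        stop("covariate_model$", param, ": unknown arm(s) ",
             paste(unknown, collapse = ", "))
      }
    }
    X <- matrix(1, nrow = length(rows), ncol = 1L)
    labels <- "(typical)"
    for (a in covs) {
      X <- cbind(X, as.numeric(prep$arm[rows] == a))
      labels <- c(labels, a)
    }
    list(X = X, XtX = crossprod(X), rows = rows, labels = labels)
  }
  eff_rows <- which(prep$treated)
  list(k = blk("k_growth", seq_len(prep$n), "vehicle"),
       vmax = blk("v_max", seq_len(prep$n), "vehicle"),
       eff = if (length(eff_rows)) blk("eff", eff_rows, treated_arms[1]) else NULL)
}

## Population means per animal given block coefficients.
.block_mu <- function(prep, blocks, beta) {
  mu <- matrix(0, prep$n, 3L)
  mu[, 1L] <- blocks$k$X %*% beta$k
  mu[, 2L] <- blocks$vmax$X %*% beta$vmax
  if (!is.null(blocks$eff)) {
    mu[blocks$eff$rows, 3L] <- blocks$eff$X %*% beta$eff
  }
  mu
}

.default_init <- function(prep) {
  ## crude but scale-aware starting values from the raw data
  vmax0 <- 1.5 * max(prep$y)
  list(k = 0.3, vmax = vmax0, eff = 0.3, gamma = 0.5,
       omega = c(0.3, 0.3, 0.3), sig_add = 5, sig_prop = 0.2)
}

#' Fit the population Gompertz model by SAEM
#'
#' Stochastic approximation EM estimation of the nonlinear mixed-effects
#' Gompertz model. Each iteration alternates (i) Metropolis sampling of
#' every animal's log-scale individual parameters from their conditional
#' posterior under the current population law — one independent proposal
#' from the population distribution plus component-wise random-walk sweeps
#' with acceptance-rate adaptation — and (ii) stochastic-approximation
#' updates of the population coefficients and random-effect variances
#' (closed-form weighted least squares on smoothed sufficient statistics)
#' and of the fixed effects `gamma` (one-dimensional profile step) and the
#' residual error parameters (damped conditional maximization).
#'
#' The vehicle arm carries no information about the treatment effect `eff`;
#' `gamma` has no random effect. The earliest observation of each animal
#' fixes its initial volume and is excluded from the residual likelihood.
#'
#' @param data growth data frame (`animal_id`, `arm`, `time_day`,
#'   `volume_mm3`) or a path to its CSV serialization.
#' @param control a [saem_control()] object.
#' @return an object of class `"saem_fit"` with components `estimates`
#'   (a [population_params()]), `covariate_effects` (named multiplicative
#'   coefficients, if a covariate model was used), `trace` (iteration
#'   history), `phi` (last sampled individual parameters), `accept`
#'   (Metropolis acceptance rates), `data`, `control`, and `loglik`
#'   (`NA` until [log_likelihood()] is called).
#' @seealso [two_stage_fit()] for the non-pooled oracle used as default
#'   initialization, [log_likelihood()], [lrt()], [predict_intervals()].
#' @export
saem_fit <- function(data, control = saem_control()) {
  if (is.character(data)) data <- read_growth_data(data)
  stopifnot(inherits(control, "saem_control"))
  prep <- .prep_growth(data, untreated_arms = control$untreated_arms)
  blocks <- .build_blocks(prep, control$covariate_model)
  has_eff <- !is.null(blocks$eff)

  ## --- initial values -------------------------------------------------
  init <- control$init
  if (is.null(init)) {
    init <- tryCatch(
      two_stage_fit(data, min_obs = 3, quiet = TRUE,
                    untreated_arms = control$untreated_arms),
      error = function(e) NULL)
  }
  if (inherits(init, "population_params")) {
    ini <- list(k = min(max(init$k_growth_mean, 1e-3), 50),
                vmax = min(max(init$v_max_mean, max(prep$v0) * 1.1),
                           exp(prep$log_vmax_hi) / 2),
                eff = max(init$eff_mean, 1e-3, na.rm = TRUE),
                gamma = min(max(init$gamma, 0.05), 2.5),
                ## wild initial spreads put the sampler on the degenerate
                ## exponential-growth ridge; cap them
                omega = pmin(pmax(c(init$omega_k, init$omega_vmax,
                                    init$omega_eff), 0.1), 1.5),
                sig_add = max(init$sigma_add, 0.5),
                sig_prop = min(max(init$sigma_prop, 0.02), 1))
    ini$omega[is.na(ini$omega)] <- 0.3
    if (is.na(ini$eff)) ini$eff <- 0.3
  } else {
    ini <- .default_init(prep)
  }

  beta <- list(k = c(log(ini$k), rep(0, ncol(blocks$k$X) - 1L)),
               vmax = c(log(ini$vmax), rep(0, ncol(blocks$vmax$X) - 1L)),
               eff = if (has_eff)
                 c(log(ini$eff), rep(0, ncol(blocks$eff$X) - 1L)))
  omega <- ini$omega                      # sd of log k, log vmax, log eff
  gamma <- ini$gamma
  sig_add <- ini$sig_add
  sig_prop <- ini$sig_prop

  n_tot <- control$n_burnin + control$n_iter
  omega_floor <- 1e-3

  with_seed(control$seed, {
    mu <- .block_mu(prep, blocks, beta)
    phi <- mu
    ll_y <- .obs_loglik(prep, phi, gamma, sig_add, sig_prop)

    ## sufficient statistics (initialized on first iteration)
    S1 <- list(); S2 <- list(k = NA_real_, vmax = NA_real_, eff = NA_real_)
    rw_sd <- c(0.3, 0.3, 0.4)             # proposal sds, adapted in burn-in
    rw_sd_ridge <- 0.3
    acc_ridge <- prop_ridge <- 0
    acc_count <- prop_count <- c(0, 0, 0)
    comps <- if (has_eff) 1:3 else 1:2

    trace <- matrix(NA_real_, n_tot, 8L + (has_eff * 0L))
    colnames(trace) <- c("k_growth_mean", "v_max_mean", "eff_mean",
                         "omega_k", "omega_vmax", "omega_eff",
                         "gamma", "sigma_prop")

    ## Polyak-style averaging of the final quarter of the smoothing phase
    ## removes the residual Monte-Carlo jitter of the SAEM chain
    n_avg <- max(20L, ceiling(control$n_iter / 4))
    n_avg <- min(n_avg, control$n_iter)
    avg <- NULL; n_seen <- 0L

    for (iter in seq_len(n_tot)) {
      burn <- iter <= control$n_burnin
      step <- if (burn) 1 else (iter - control$n_burnin)^(-control$sa_exponent)
      mu <- .block_mu(prep, blocks, beta)

      ## ---- (i) Metropolis within Gibbs over individuals --------------
      ## kernel A: independent proposal from the population law
      phi_star <- mu + matrix(stats::rnorm(prep$n * 3L), prep$n, 3L) %*%
        diag(omega)
      ll_star <- .obs_loglik(prep, phi_star, gamma, sig_add, sig_prop)
      acc <- log(stats::runif(prep$n)) < (ll_star - ll_y)
      phi[acc, ] <- phi_star[acc, ]
      ll_y[acc] <- ll_star[acc]

      ## kernel B: component-wise random walks
      for (sweep in seq_len(control$n_kernels)) {
        for (cc in comps) {
          phi_star <- phi
          live <- if (cc == 3L) prep$treated else rep(TRUE, prep$n)
          phi_star[live, cc] <- phi[live, cc] +
            rw_sd[cc] * stats::rnorm(sum(live))
          ll_star <- .obs_loglik(prep, phi_star, gamma, sig_add, sig_prop)
          dprior <- stats::dnorm(phi_star[, cc], mu[, cc], omega[cc],
                                 log = TRUE) -
            stats::dnorm(phi[, cc], mu[, cc], omega[cc], log = TRUE)
          acc <- live & (log(stats::runif(prep$n)) <
                           (ll_star - ll_y + dprior))
          phi[acc, cc] <- phi_star[acc, cc]
          ll_y[acc] <- ll_star[acc]
          acc_count[cc] <- acc_count[cc] + sum(acc)
          prop_count[cc] <- prop_count[cc] + sum(live)
        }
      }
      ## kernel C (treated animals): random walk along the k/eff ridge.
      ## The likelihood depends on k and eff only through
      ## k_eff = k (1 - eff); moving log k while holding k_eff fixed
      ## leaves it unchanged, so acceptance involves only the priors and
      ## the Jacobian exp(-(phi_k + phi_eff)) of the (phi_k, k_eff)
      ## parameterization. This decorrelates the otherwise ridge-locked
      ## pair at no likelihood cost.
      if (has_eff) {
        tr_i <- which(prep$treated)
        for (sweep in seq_len(3L)) {
          d <- rw_sd_ridge * stats::rnorm(length(tr_i))
          pk <- phi[tr_i, 1L]; pe <- phi[tr_i, 3L]
          pk_star <- pk + d
          one_m_eff_star <- (1 - exp(pe)) * exp(-d)
          ## eff* <= 0 yields NaN and is rejected below
          pe_star <- suppressWarnings(log(1 - one_m_eff_star))
          okr <- is.finite(pe_star) & pe_star <= prep$log_eff_hi &
            pk_star >= prep$log_k_lo & pk_star <= prep$log_k_hi
          lr <- stats::dnorm(pk_star, mu[tr_i, 1L], omega[1L], log = TRUE) -
            stats::dnorm(pk, mu[tr_i, 1L], omega[1L], log = TRUE) +
            stats::dnorm(pe_star, mu[tr_i, 3L], omega[3L], log = TRUE) -
            stats::dnorm(pe, mu[tr_i, 3L], omega[3L], log = TRUE) -
            (pk_star + pe_star) + (pk + pe)
          accr <- okr & log(stats::runif(length(tr_i))) < lr
          phi[tr_i[accr], 1L] <- pk_star[accr]
          phi[tr_i[accr], 3L] <- pe_star[accr]
          acc_ridge <- acc_ridge + sum(accr)
          prop_ridge <- prop_ridge + length(tr_i)
        }
      }

      ## adapt proposal scales towards ~30% acceptance during burn-in
      if (burn && iter %% 25L == 0L) {
        rate <- acc_count / pmax(prop_count, 1)
        rw_sd <- rw_sd * exp(0.5 * (rate - 0.3))
        rw_sd <- pmin(pmax(rw_sd, 1e-4), 2)
        acc_count <- prop_count <- c(0, 0, 0)
        if (prop_ridge > 0) {
          rw_sd_ridge <- min(max(
            rw_sd_ridge * exp(0.5 * (acc_ridge / prop_ridge - 0.3)),
            1e-4), 2)
          acc_ridge <- prop_ridge <- 0
        }
      }

      ## ---- (ii) stochastic approximation + M-step --------------------
      for (p in c("k", "vmax", if (has_eff) "eff")) {
        b <- blocks[[p]]
        col <- switch(p, k = 1L, vmax = 2L, eff = 3L)
        ph <- phi[b$rows, col]
        s1 <- drop(crossprod(b$X, ph)); s2 <- sum(ph^2)
        if (iter == 1L) { S1[[p]] <- s1; S2[[p]] <- s2 }
        S1[[p]] <- S1[[p]] + step * (s1 - S1[[p]])
        S2[[p]] <- S2[[p]] + step * (s2 - S2[[p]])
        beta_new <- drop(solve(b$XtX, S1[[p]]))
        v <- (S2[[p]] - 2 * sum(beta_new * S1[[p]]) +
                drop(t(beta_new) %*% b$XtX %*% beta_new)) / nrow(b$X)
        v <- max(v, omega_floor^2)
        if (burn) v <- max(v, 0.95 * omega[col]^2)  # annealed decrease
        beta[[p]] <- beta_new
        omega[col] <- sqrt(v)
      }

      ## gamma: one-dimensional profile of the conditional likelihood
      gfun <- function(g) {
        f <- .obs_pred(prep, phi, g)
        -sum(stats::dnorm(prep$y, f,
                          sqrt(sig_add^2 + (sig_prop * f)^2), log = TRUE))
      }
      ghat <- stats::optimize(gfun, c(0.02, 3), tol = 1e-4)$minimum
      gamma <- gamma + step * (ghat - gamma)

      ## residual error: damped conditional maximization given phi, gamma
      f <- .obs_pred(prep, phi, gamma)
      rfun <- function(par) {
        sd <- sqrt(exp(par[1])^2 + (exp(par[2]) * f)^2)
        -sum(stats::dnorm(prep$y, f, sd, log = TRUE))
      }
      ropt <- stats::optim(c(log(sig_add), log(sig_prop)), rfun,
                           method = "Nelder-Mead",
                           control = list(maxit = 60))
      sa_new <- exp(ropt$par[1]); sp_new <- exp(ropt$par[2])
      if (burn) sp_new <- max(sp_new, 0.95 * sig_prop)
      sig_add <- sig_add + step * (sa_new - sig_add)
      sig_prop <- sig_prop + step * (sp_new - sig_prop)
      sig_add <- max(sig_add, 1e-3)
      sig_prop <- max(sig_prop, 1e-4)

      if (iter > n_tot - n_avg) {
        state <- c(unlist(beta), omega, gamma, sig_add, sig_prop)
        avg <- if (is.null(avg)) state else avg + state
        n_seen <- n_seen + 1L
      }

      trace[iter, ] <- c(exp(beta$k[1]), exp(beta$vmax[1]),
                         if (has_eff) exp(beta$eff[1]) else NA_real_,
                         omega[1], omega[2],
                         if (has_eff) omega[3] else NA_real_,
                         gamma, sig_prop)
      if (control$verbose && iter %% 50L == 0L) {
        message(sprintf("SAEM iter %d/%d  k=%.3f vmax=%.0f eff=%s gamma=%.3f",
                        iter, n_tot, exp(beta$k[1]), exp(beta$vmax[1]),
                        if (has_eff) sprintf("%.3f", exp(beta$eff[1])) else "-",
                        gamma))
      }
    }

    ## unpack the tail-averaged state
    avg <- avg / n_seen
    pos <- 0L
    for (p in c("k", "vmax", if (has_eff) "eff")) {
      q <- length(beta[[p]])
      beta[[p]] <- unname(avg[pos + seq_len(q)])
      pos <- pos + q
    }
    omega <- unname(avg[pos + 1:3]); pos <- pos + 3L
    gamma <- unname(avg[pos + 1L])
    sig_add <- unname(avg[pos + 2L])
    sig_prop <- unname(avg[pos + 3L])

    rate <- acc_count / pmax(prop_count, 1)
    if (all(prop_count > 0) && any(rate[comps] < 0.01)) {
      warning("Metropolis acceptance nearly zero for component(s): ",
              paste(c("k", "vmax", "eff")[comps][rate[comps] < 0.01],
                    collapse = ", "))
    }

    est <- population_params(
      k_growth_mean = exp(beta$k[1]), omega_k = omega[1],
      v_max_mean = exp(beta$vmax[1]), omega_vmax = omega[2],
      eff_mean = if (has_eff) exp(beta$eff[1]) else 1e-12,
      omega_eff = if (has_eff) omega[3] else 0,
      gamma = gamma, sigma_prop = sig_prop, sigma_add = sig_add)

    cov_eff <- list()
    for (p in c("k", "vmax", if (has_eff) "eff")) {
      b <- blocks[[p]]
      if (length(b$labels) > 1L) {
        pn <- switch(p, k = "k_growth", vmax = "v_max", eff = "eff")
        for (j in 2:length(b$labels)) {
          cov_eff[[paste(pn, b$labels[j], sep = ":")]] <- exp(beta[[p]][j])
        }
      }
    }

    structure(list(estimates = est, covariate_effects = cov_eff,
                   beta = beta, omega = omega,
                   has_eff = has_eff,
                   n_model_params = length(beta$k) + length(beta$vmax) +
                     (if (has_eff) length(beta$eff) else 0L) +
                     sum(omega[comps] > 0) + 3L, # + gamma, sig_add, sig_prop
                   trace = as.data.frame(trace),
                   phi = phi, accept = rate,
                   data = data, control = control,
                   loglik = NA_real_, loglik_se = NA_real_),
              class = "saem_fit")
  })
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("Population Gompertz fit (SAEM), ",
      length(unique(x$data$animal_id)), " animals\n", sep = "")
  print(x$estimates)
  if (length(x$covariate_effects)) {
    cat("Covariate effects (multiplicative):\n")
    for (nm in names(x$covariate_effects)) {
      cat(sprintf("  %s : %.4g\n", nm, x$covariate_effects[[nm]]))
    }
  }
  if (is.finite(x$loglik)) {
    cat(sprintf("Log-likelihood (importance sampling): %.2f (se %.2f)\n",
                x$loglik, x$loglik_se))
  }
  invisible(x)
}
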