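#' Tumour volume from caliper measurements
#'
#' Converts two perpendicular caliper diameters into an approximate tumour
#' volume using the standard ellipsoid formula \eqn{V = L l^2 / 2}, with
#' `L` the longest diameter and `l` the perpendicular one (both in mm).
#'
#' @param L numeric vector, longest diameter (mm).
#' @param l numeric vector, perpendicular diameter (mm); must satisfy
#'   `0 <= l <= L` elementwise.
#' @return numeric vector of volumes in mm^3.
#' @examples
#' volume_from_caliper(10, 4) # 80 mm^3
#' @export
volume_from_caliper <- function(L, l) {
  if (!is.numeric(L) || !is.numeric(l)) {
    stop("caliper diameters must be numeric")
  }
  if (any(!is.finite(L)) || any(!is.finite(l))) {
    stop("caliper diameters must be finite")
  }
  if (any(l < 0)) stop("perpendicular diameter l must be non-negative")
  if (any(L < l)) stop("longest diameter L must be >= perpendicular diameter l")
  L * l^2 / 2
}

#' Individual Gompertz growth parameters
#'
#' Bundles the parameters of the generalized Gompertz growth law
#' \deqn{dV/dt = k_{eff}(t) \, V \, [\log(V_{max}/V)]^\gamma}
#' for a single animal, together with its treatment-effect parameter.
#' `eff = 0` means no treatment effect; under treatment the growth rate is
#' multiplied by `1 - eff`.
#'
#' @param k_growth first-order growth rate constant (1/day), > 0.
#' @param v_max maximum (plateau) tumour volume (mm^3), > 0.
#' @param gamma dimensionless power coefficient, > 0; `gamma = 1` is the
#'   classic Gompertz law.
#' @param eff dimensionless treatment effect, >= 0 (0 = untreated behaviour).
#' @param v0 volume at the time origin (mm^3), with `0 < v0 <= v_max`.
#' @return an object of class `"gompertz_params"` (a named list).
#' @export
gompertz_params <- function(k_growth, v_max, gamma = 1, eff = 0, v0) {
  stopifnot(is.numeric(k_growth), is.numeric(v_max), is.numeric(gamma),
            is.numeric(eff), is.numeric(v0))
  if (k_growth <= 0) stop("k_growth must be > 0")
  if (v_max <= 0) stop("v_max must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (eff < 0) stop("eff must be >= 0")
  if (v0 <= 0) stop("v0 must be > 0")
  if (v0 > v_max) stop("v0 must not exceed v_max")
  structure(list(k_growth = k_growth, v_max = v_max, gamma = gamma,
                 eff = eff, v0 = v0),
            class = "gompertz_params")
}

#' Treatment schedule metadata
#'
#' Describes whether and when an animal is treated. Treatment is modelled as
#' continuously active from `start_time` onward; the dosing interval (i.p.
#' injections every two days in the emulated design) is carried as metadata
#' only, since no pharmacokinetic model is fitted.
#'
#' @param treated logical flag.
#' @param start_time day at which treatment starts (>= 0).
#' @param dosing_interval days between doses (metadata, > 0).
#' @return an object of class `"treatment_schedule"`.
#' @export
treatment_schedule <- function(treated = FALSE, start_time = 0,
                               dosing_interval = 2) {
  stopifnot(is.logical(treated), length(treated) == 1L)
  if (start_time < 0) stop("start_time must be >= 0")
  if (dosing_interval <= 0) stop("dosing_interval must be > 0")
  structure(list(treated = treated, start_time = start_time,
                 dosing_interval = dosing_interval),
            class = "treatment_schedule")
}

#' Effective growth rate under treatment
#'
#' The treatment effect acts multiplicatively on the growth rate constant:
#' a treated animal grows at `k_growth * (1 - eff)`, so the untreated to
#' treated rate ratio is `1 / (1 - eff)`. `eff >= 1` (growth arrest or
#' tumour shrinkage) is only admitted when `shrinkage = TRUE`.
#'
#' @param k_growth growth rate constant (1/day), > 0.
#' @param eff treatment effect, >= 0.
#' @param treated logical; is treatment active?
#' @param shrinkage allow `eff >= 1` (zero or negative effective rate)?
#' @return effective growth rate (1/day).
#' @examples
#' effective_growth_rate(0.64, eff = 0.52, treated = TRUE) # 0.64 * 0.48
#' @export
effective_growth_rate <- function(k_growth, eff, treated, shrinkage = FALSE) {
  if (any(k_growth <= 0)) stop("k_growth must be > 0")
  if (any(eff < 0)) stop("eff must be >= 0")
  if (!shrinkage && any(treated & eff >= 1)) {
    stop("eff >= 1 under treatment implies growth arrest/shrinkage; ",
         "set shrinkage = TRUE to allow it")
  }
  ifelse(treated, k_growth * (1 - eff), k_growth)
}

## Closed-form solution of du/dt = -k u^gamma, u(0) = u0 >= 0,
## where u = log(v_max / V). Vectorized over everything.
## gamma < 1: u reaches 0 (the plateau) in finite time; gamma > 1 with k < 0
## (shrinkage) can push V towards 0, where u is capped for stability.
.gomp_u <- function(u0, k, gamma, t) {
  if (gamma == 1) {
    return(u0 * exp(-k * t))
  }
  e <- 1 - gamma
  w <- u0^e - k * e * t
  if (e > 0) {
    ## gamma < 1: w <= 0 means the plateau has been reached
    u <- pmax(w, 0)^(1 / e)
  } else {
    ## gamma > 1: w > 0 for growing tumours; cap to avoid 0^(negative)
    u <- pmax(w, 1e-300)^(1 / e)
  }
  ## u0 == 0 is a fixed point of the ODE
  u[u0 == 0] <- 0
  u
}

## Piecewise trajectory for one animal: constant rate k0 before `s`,
## k1 afterwards. times need not be sorted here.
.gomp_volume_analytic <- function(times, v0, v_max, gamma, k0, k1, s) {
  u0 <- log(v_max / v0)
  u <- numeric(length(times))
  pre <- times <= s
  u[pre] <- .gomp_u(u0, k0, gamma, times[pre])
  if (any(!pre)) {
    us <- .gomp_u(u0, k0, gamma, s)
    u[!pre] <- .gomp_u(us, k1, gamma, times[!pre] - s)
  }
  v_max * exp(-u)
}

.gomp_volume_ode <- function(times, v0, v_max, gamma, k0, k1, s,
                             atol = 1e-8, rtol = 1e-8) {
  rhs <- function(t, y, parms) {
    k <- if (t < parms$s) parms$k0 else parms$k1
    v <- min(max(y[1], 1e-12), v_max)
    list(k * v * max(log(v_max / v), 0)^gamma)
  }
  tgrid <- sort(unique(c(0, times, if (s > 0 && s < max(times)) s)))
  sol <- deSolve::ode(y = c(V = v0), times = tgrid, func = rhs,
                      parms = list(k0 = k0, k1 = k1, s = s),
                      method = "lsoda", atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration of the Gompertz model failed (istate = ",
         attr(sol, "istate")[1], ")")
  }
  sol[match(times, tgrid), "V"]
}

#' Predict a deterministic Gompertz volume trajectory
#'
#' Solves \eqn{dV/dt = k_{eff}(t) V [\log(V_{max}/V)]^\gamma} with
#' \eqn{V(0) = v_0}, where the effective rate switches from `k_growth` to
#' `k_growth * (1 - eff)` at the treatment start time. The default
#' `"analytic"` method uses the exact solution of the ODE (obtained by the
#' substitution \eqn{u = \log(V_{max}/V)}); `"ode"` integrates numerically
#' with an adaptive solver, forcing the treatment start as a step boundary.
#'
#' @param params a [gompertz_params()] object.
#' @param schedule a [treatment_schedule()] object.
#' @param times non-negative, non-decreasing vector of days.
#' @param method `"analytic"` (exact) or `"ode"` (numerical integration,
#'   absolute and relative tolerance 1e-8).
#' @param shrinkage allow `eff >= 1` (see [effective_growth_rate()]).
#' @return numeric vector of volumes (mm^3), one per time.
#' @export
predict_volume <- function(params, schedule = treatment_schedule(),
                           times, method = c("analytic", "ode"),
                           shrinkage = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(params, "gompertz_params"),
            inherits(schedule, "treatment_schedule"))
  if (length(times) == 0) return(numeric(0))
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted non-decreasing")
  k0 <- params$k_growth
  k1 <- effective_growth_rate(params$k_growth, params$eff,
                              treated = schedule$treated,
                              shrinkage = shrinkage)
  s <- if (schedule$treated) schedule$start_time else Inf
  if (s == 0) { k0 <- k1 }
  f <- switch(method,
              analytic = .gomp_volume_analytic,
              ode = .gomp_volume_ode)
  f(times, params$v0, params$v_max, params$gamma, k0, k1, s)
}
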