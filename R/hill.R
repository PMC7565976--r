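#' Normalize currents to a reference concentration
#'
#' Expresses raw responses (e.g. whole-cell current amplitudes in pA) as a
#' ratio of the response at a reference concentration — typically the
#' maximal response, as when ATP-evoked currents are expressed relative to
#' the 10 mM response. When a `cell_id` column is present, each cell is
#' normalized to its own reference response.
#'
#' @param data data frame with columns `concentration_mM`, `current`
#'   (raw response) and optionally `cell_id`.
#' @param reference_concentration concentration whose response maps to 1.
#' @return the data frame with an added `response` column.
#' @export
normalize_currents <- function(data, reference_concentration) {
  need <- c("concentration_mM", "current")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!("cell_id" %in% names(data))) data$cell_id <- "cell_01"
  split_idx <- split(seq_len(nrow(data)), data$cell_id)
  data$response <- NA_real_
  for (rows in split_idx) {
    ref <- rows[data$concentration_mM[rows] == reference_concentration]
    if (!length(ref)) {
      stop("reference concentration ", reference_concentration,
           " mM absent for cell ", data$cell_id[rows[1]])
    }
    refcur <- mean(data$current[ref])
    if (!is.finite(refcur) || refcur == 0) {
      stop("zero/invalid reference current for cell ", data$cell_id[rows[1]])
    }
    data$response[rows] <- data$current[rows] / refcur
  }
  data
}

#' Fit the Hill equation to concentration-response data
#'
#' Least-squares fit of \eqn{r(c) = top \cdot c^n / (c^n + EC_{50}^n)} to
#' normalized responses, estimating the half-maximal concentration
#' `ec50`, the Hill coefficient `hill_n` and the maximal response `top`
#' (bounded in (0, 1.5] since responses are normalized to a reference).
#' A deterministic multi-start — log-spaced `ec50` candidates in
#' [0.1, 30] mM crossed with Hill coefficients {0.5, 1, 1.5, 2, 3} —
#' guards against local minima; the best start is polished by
#' Gauss-Newton.
#'
#' @param concentrations vector of concentrations (mM), or a data frame
#'   with columns `concentration_mM` and `response` (and optionally
#'   `cell_id`; replicates are allowed and pooled).
#' @param responses normalized responses (ignored when `concentrations`
#'   is a data frame).
#' @return an object of class `"hill_fit"`: `ec50`, `hill_n`, `top`,
#'   `residual_sse`, `n_points`.
#' @export
fit_hill <- function(concentrations, responses = NULL) {
  if (is.data.frame(concentrations)) {
    df <- concentrations
    need <- c("concentration_mM", "response")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    conc <- df$concentration_mM; resp <- df$response
  } else {
    conc <- concentrations; resp <- responses
  }
  if (length(conc) != length(resp)) stop("length mismatch")
  keep <- is.finite(conc) & is.finite(resp) & conc > 0
  conc <- conc[keep]; resp <- resp[keep]
  if (length(unique(conc)) < 3) stop("need >= 3 distinct concentrations")

  sse <- function(par) {
    ec50 <- exp(par[1]); n <- exp(par[2]); top <- par[3]
    if (top <= 0 || top > 1.5) return(1e10)
    f <- top * conc^n / (conc^n + ec50^n)
    sum((resp - f)^2)
  }
  starts <- expand.grid(
    lec = log(exp(seq(log(0.1), log(30), length.out = 8))),
    ln = log(c(0.5, 1, 1.5, 2, 3)),
    top = min(max(max(resp), 0.2), 1.5))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[s, ]), sse, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("Hill fit failed to converge; best candidate: ec50 = ",
         signif(exp(best$par[1]), 3))
  }
  ## Gauss-Newton polish (port algorithm); fall back to the optim optimum
  pol <- tryCatch({
    fitdat <- data.frame(c = conc, r = resp)
    nl <- suppressWarnings(stats::nls(r ~ top * c^n / (c^n + ec50^n), data = fitdat,
                     start = list(ec50 = exp(best$par[1]),
                                  n = exp(best$par[2]), top = best$par[3]),
                     algorithm = "port",
                     lower = c(ec50 = 1e-6, n = 1e-3, top = 1e-6),
                     upper = c(ec50 = 1e4, n = 50, top = 1.5),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE)))
    cf <- stats::coef(nl)
    list(par = c(log(cf[["ec50"]]), log(cf[["n"]]), cf[["top"]]),
         value = sum(stats::resid(nl)^2))
  }, error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value) {
    best <- pol
  }
  structure(list(ec50 = exp(best$par[1]), hill_n = exp(best$par[2]),
                 top = best$par[3], residual_sse = best$value,
                 n_points = length(conc)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("Hill fit: EC50 = %.3g mM, n = %.3g, top = %.3g ",
                     "(SSE %.3g, %d points)\n"),
              x$ec50, x$hill_n, x$top, x$residual_sse, x$n_points))
  invisible(x)
}
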