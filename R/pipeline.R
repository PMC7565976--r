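#' Run an end-to-end analysis pipeline
#'
#' Executes one of four scenarios and writes a report bundle to `out_dir`:
#'
#' * `"simulate-then-fit"` — simulate a cohort from the configured design
#'   and population values, fit it by SAEM, run the configured
#'   likelihood-ratio tests, and (optionally) compute prediction bands.
#' * `"fit-only"` — fit a user-supplied growth CSV.
#' * `"hill"` — fit the Hill equation to a dose-response CSV (or to
#'   simulated data when none is given).
#' * `"survival"` — Gehan-Breslow-Wilcoxon comparisons of treated arms
#'   against the reference group of a survival CSV.
#'
#' The bundle always contains `report.json` (validated against the schema
#' shipped in `inst/schema/report.schema.json`) plus scenario-specific
#' CSV/JSON artifacts. Identical config and seed give byte-identical
#' JSON output.
#'
#' @param config a named list, or path to a YAML/JSON file mirroring the
#'   constructor arguments: `scenario`; `design` and `population`
#'   (argument lists for [study_design()] / [population_params()]);
#'   `growth_csv`, `dose_csv`, `survival_csv` input paths; `saem`
#'   (argument list for [saem_control()]); `lrt_covariates` (covariate
#'   model for an alternative model to test); `hill_truth`
#'   (`ec50`, `hill_n`, `concentrations`, `n_cells`, `noise_sd`);
#'   `predict` (logical).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed applied to every stochastic stage.
#' @return the report (a named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("tumgrowth_"),
                         seed = 1L) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$scenario) ||
      !config$scenario %in% c("simulate-then-fit", "fit-only", "hill",
                              "survival")) {
    stop("config$scenario must be one of simulate-then-fit, fit-only, ",
         "hill, survival")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    scenario = config$scenario,
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("tumgrowth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  scen <- config$scenario
  if (scen %in% c("simulate-then-fit", "fit-only")) {
    if (scen == "simulate-then-fit") {
      design <- do.call(study_design, config$design %||% list())
      pop <- do.call(population_params, config$population %||% list())
      sim <- simulate_cohort(design, pop, seed = seed)
      if (is.null(sim$growth)) stop("empty design: no animals simulated")
      growth <- sim$growth
      write_growth_data(growth, file.path(out_dir, "growth.csv"))
      write_survival_data(sim$survival, file.path(out_dir, "survival.csv"))
    } else {
      if (is.null(config$growth_csv)) stop("fit-only needs growth_csv")
      growth <- read_growth_data(config$growth_csv)
    }
    ctrl_args <- config$saem %||% list()
    ctrl_args$seed <- seed + 1L
    ctrl <- do.call(saem_control, ctrl_args)
    fit <- saem_fit(growth, ctrl)
    report$fit <- list(
      estimates = unclass(fit$estimates),
      covariate_effects = fit$covariate_effects,
      accept = as.list(stats::setNames(fit$accept, c("k", "vmax", "eff"))))
    utils::write.csv(fit$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    report$treatment_slowing_factor <-
      if (fit$has_eff && fit$estimates$eff_mean < 1) {
        1 / (1 - fit$estimates$eff_mean)
      } else NA
    if (!is.null(config$lrt_covariates)) {
      fit <- log_likelihood(fit, seed = seed + 2L)
      ctrl_alt <- ctrl
      ctrl_alt$covariate_model <- config$lrt_covariates
      ctrl_alt$seed <- seed + 3L
      fit_alt <- saem_fit(growth, ctrl_alt)
      fit_alt <- log_likelihood(fit_alt, seed = seed + 4L)
      lr <- lrt(fit, fit_alt)
      report$lrt <- list(statistic = lr$statistic, df = lr$df,
                         p_value = lr$p_value)
      jsonlite::write_json(report$lrt, file.path(out_dir, "lrt.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (isTRUE(config$predict)) {
      pred_design <- if (scen == "simulate-then-fit") design else
        study_design(arms = unique(growth$arm))
      band <- predict_intervals(fit, pred_design, seed = seed + 5L)
      utils::write.csv(band, file.path(out_dir, "prediction_band.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report$fit, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (scen == "hill") {
    if (!is.null(config$dose_csv)) {
      dr <- utils::read.csv(config$dose_csv, stringsAsFactors = FALSE)
    } else {
      ht <- config$hill_truth %||% list()
      dr <- simulate_dose_response(
        ec50 = ht$ec50 %||% 4.3, hill_n = ht$hill_n %||% 1.5,
        concentrations = ht$concentrations %||% c(0.3, 1, 3, 5, 10),
        n_cells = ht$n_cells %||% 6, noise_sd = ht$noise_sd %||% 0.05,
        seed = seed)
      utils::write.csv(dr, file.path(out_dir, "dose_response.csv"),
                       row.names = FALSE)
    }
    hf <- fit_hill(dr)
    report$hill <- list(ec50 = hf$ec50, hill_n = hf$hill_n, top = hf$top,
                        residual_sse = hf$residual_sse)
    jsonlite::write_json(report$hill, file.path(out_dir, "hill.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (scen == "survival") {
    if (is.null(config$survival_csv)) stop("survival scenario needs survival_csv")
    sv <- read_survival_data(config$survival_csv)
    ref <- config$reference_group %||% "vehicle"
    others <- setdiff(unique(sv$group), ref)
    if (!length(others)) stop("need at least one non-reference group")
    report$survival <- lapply(others, function(g) {
      ts <- gehan_breslow_wilcoxon(sv, g, ref, p_method = "both",
                                   seed = seed)
      list(group = g, reference = ref, statistic = ts$statistic,
           chi_square = ts$chi_square, p_value = ts$p_value,
           p_permutation = ts$p_permutation)
    })
    jsonlite::write_json(report$survival,
                         file.path(out_dir, "survival_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  validate_report(report)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report produced by [run_pipeline()] against the JSON schema
#' in `inst/schema/report.schema.json` (required keys, value types, and
#' the scenario enumeration).
#'
#' @param report a report list, or path to a `report.json`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  schema_path <- system.file("schema", "report.schema.json",
                             package = "tumgrowth")
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  for (key in schema$required) {
    if (is.null(report[[key]])) stop("report lacks required key: ", key)
  }
  if (!report$scenario %in% schema$properties$scenario$enum) {
    stop("report scenario not in schema enumeration: ", report$scenario)
  }
  if (!is.numeric(report$seed)) stop("report seed must be numeric")
  if (!is.character(report$package_version)) {
    stop("report package_version must be a string")
  }
  if (!is.null(report$fit)) {
    est <- report$fit$estimates
    for (key in c("k_growth_mean", "v_max_mean", "gamma")) {
      if (!is.numeric(est[[key]])) stop("fit estimates lack numeric ", key)
    }
  }
  if (!is.null(report$lrt)) {
    if (!is.numeric(report$lrt$p_value) || report$lrt$p_value < 0 ||
        report$lrt$p_value > 1) {
      stop("lrt p_value must be a probability")
    }
  }
  invisible(TRUE)
}
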