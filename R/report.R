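# Configuration surface and reports. Config keys mirror the reference
# argument table: eta, BFthres, eff.size, m, t.points, beta1, log,
# var.u0, var.u1, var.e, cov, fraction, sensitivity, hyp, test, seed,
# plus log.shift, Nmin, Nmax.

config_defaults <- function() {
  list(
    eta = 0.8, BFthres = 3, eff.size = 0.8, m = 1000,
    t.points = c(0, 1, 2, 3, 4), beta1 = 0, log = FALSE,
    var.u0 = 0.03, var.u1 = 0.1, var.e = 0.02, cov = 0,
    fraction = 1, sensitivity = FALSE, hyp = "both", test = "alt",
    seed = NULL,
    log.shift = 0, Nmin = 30, Nmax = 1000
  )
}

normalize_hyp <- function(x) {
  switch(tolower(as.character(x)),
         "h0" = "H0", "h1" = "H1", "both" = "both", "b" = "both",
         abort(sprintf(
           "invalid `hyp` value %s; valid values are \"h0\"/\"H0\", \"h1\"/\"H1\", \"both\"/\"b\".", x),
           class = "growthssd_config"))
}

normalize_test <- function(x) {
  switch(tolower(as.character(x)),
         "alt" = "alt", "hc" = "Hc", "hu" = "Hu",
         abort(sprintf(
           "invalid `test` value %s; valid values are \"alt\", \"Hc\"/\"hc\", \"Hu\"/\"hu\".", x),
           class = "growthssd_config"))
}

#' Read a configuration file
#'
#' YAML or JSON with the reference argument names (`eta`, `BFthres`,
#' `eff.size`, `m`, `t.points`, `beta1`, `log`, `var.u0`, `var.u1`,
#' `var.e`, `cov`, `fraction`, `sensitivity`, `hyp`, `test`, `seed`, and
#' optionally `log.shift`, `Nmin`, `Nmax`). Missing keys take the
#' defaults.
#'
#' @param path File path ending in `.yml`, `.yaml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  stopifnot(is.list(config))
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "growthssd_config")
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$hyp <- normalize_hyp(cfg$hyp)
  cfg$test <- normalize_test(cfg$test)
  cfg
}

design_from_config <- function(cfg, direction = "positive") {
  growth_design(
    t_points = cfg$t.points,
    log_growth = isTRUE(cfg$log), log_shift = cfg$log.shift,
    var_e = cfg$var.e, var_u0 = cfg$var.u0, var_u1 = cfg$var.u1,
    cov_u01 = cfg$cov,
    eff_size = cfg$eff.size, direction = direction,
    beta1 = cfg$beta1,
    bf_thresh = cfg$BFthres, eta = cfg$eta, m = cfg$m,
    fraction = cfg$fraction, sensitivity = isTRUE(cfg$sensitivity),
    hypothesis = cfg$hyp, test = cfg$test,
    seed = cfg$seed
  )
}

collect_warnings <- function(expr) {
  warnings <- character()
  value <- withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warnings)
}

new_run_report <- function(cfg, result, warnings, mode, elapsed) {
  structure(
    list(mode = mode, config = cfg, result = result,
         warnings = warnings,
         runtime_seconds = as.numeric(elapsed),
         created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    class = "run_report")
}

#' Run a full sample size determination from a configuration
#'
#' Resolves a configuration (list or YAML/JSON path) against the default
#' argument table, builds the design, runs [find_sample_size()] (with the
#' fraction sensitivity analysis when requested) and returns a report
#' carrying the resolved configuration, the result, and every warning
#' raised during the run.
#'
#' @param config Named list or path to a YAML/JSON file.
#' @param direction `"positive"` or `"negative"` expected interaction.
#' @param n_min,n_max Optional overrides of the search bounds.
#' @return A `run_report`; see [write_report()].
#' @examples
#' rep <- run_ssd(list(eff.size = 0.8, var.u1 = 0.003, var.e = 0.0262,
#'                     var.u0 = 0.0333, m = 30, seed = 1,
#'                     Nmin = 10, Nmax = 200))
#' rep
#' @export
run_ssd <- function(config = list(), direction = "positive",
                    n_min = NULL, n_max = NULL) {
  t0 <- Sys.time()
  cfg <- resolve_config(config)
  if (!is.null(n_min)) cfg$Nmin <- n_min
  if (!is.null(n_max)) cfg$Nmax <- n_max
  design <- design_from_config(cfg, direction)
  got <- collect_warnings(
    find_sample_size(design, n_min = cfg$Nmin, n_max = cfg$Nmax))
  new_run_report(cfg, got$value, got$warnings, "ssd",
                 difftime(Sys.time(), t0, units = "secs"))
}

#' Estimate power at a fixed sample size from a configuration
#'
#' @inheritParams run_ssd
#' @param n_subjects Total number of subjects.
#' @return A `run_report` whose result is a `bayes_power` object.
#' @export
run_power <- function(config = list(), n_subjects,
                      direction = "positive") {
  t0 <- Sys.time()
  cfg <- resolve_config(config)
  design <- design_from_config(cfg, direction)
  got <- collect_warnings(estimate_power(design, n_subjects))
  new_run_report(cfg, got$value, got$warnings, "power",
                 difftime(Sys.time(), t0, units = "secs"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %s mode, %.1f s>\n", x$mode,
              x$runtime_seconds))
  print(x$result)
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

report_payload <- function(report) {
  result <- report$result
  res <- if (inherits(result, "ssd_result")) {
    list(per_fraction = as.data.frame(result$per_b),
         trace = as.data.frame(result$trace),
         n_min = result$n_min, n_max = result$n_max,
         notes = result$notes)
  } else {
    list(power = as.data.frame(as_tibble(result)),
         n_subjects = attr(result, "n_subjects"),
         m_effective = as.list(attr(result, "m_effective")),
         excluded = as.list(attr(result, "excluded")))
  }
  cfg <- report$config
  cfg$t.points <- as.numeric(cfg$t.points)
  list(mode = report$mode, config = cfg, result = res,
       warnings = report$warnings,
       runtime_seconds = report$runtime_seconds,
       created = report$created)
}

#' Write a machine-readable run report
#'
#' Schema-stable JSON with the resolved configuration (which round-trips
#' to an identical run), the result and all warnings.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
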