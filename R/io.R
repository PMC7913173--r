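#' Export and re-import posterior draws
#'
#' Writes the retained draws as a plain CSV, one column per parameter plus
#' `.chain` and `.iteration`, so draws can be archived or summarized by other
#' tools. `read_draws_csv()` restores the tibble; [bws_summary()] on the
#' re-read tibble reproduces the fit's summaries exactly.
#'
#' @param fit A `bws_fit` object (or a draws tibble).
#' @param path Output file path.
#' @return `write_draws_csv()` returns `path` invisibly; `read_draws_csv()`
#'   returns a tibble.
#' @export
write_draws_csv <- function(fit, path) {
  draws <- if (inherits(fit, "bws_fit")) fit$draws else fit
  write.csv(draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
read_draws_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Aligned plain-text summary table
#'
#' Formats a fit summary in the conventional reporting layout
#' (Median | Mean | 95% HPD), one row per parameter.
#'
#' @param x A `bws_fit` or the tibble returned by [tidy.bws_fit()].
#' @param digits Significant digits.
#' @param ... Passed to [tidy.bws_fit()] when `x` is a fit.
#' @return A character vector of lines, invisibly; printed as a side effect.
#' @export
format_summary_table <- function(x, digits = 2, ...) {
  s <- if (inherits(x, "bws_fit")) tidy(x, ...) else x
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  lines <- c(
    sprintf("%-22s %8s %8s  %s", "Parameter", "Median", "Mean", "95% HPD"),
    sprintf("%-22s %8s %8s  (%s, %s)", s$term, fmt(s$median), fmt(s$mean),
            fmt(s$hpd_lower), fmt(s$hpd_upper)))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Scenario configuration files
#'
#' A scenario can be stored as a flat YAML file with keys matching
#' [bws_scenario()] arguments (`n`, `theta`, `weights`, `correlation`,
#' `residual_sd`, `link`, `n_replicates`, `base_seed`) plus optional sampler
#' keys (`iterations`, `burn_in`, `thin`, `chains`).
#'
#' @param path YAML file path.
#' @return `read_scenario_file()`: a list with elements `scenario` and
#'   `control`.
#' @export
read_scenario_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  sc_args <- cfg[intersect(names(cfg),
                           c("n", "theta", "weights", "correlation",
                             "residual_sd", "link", "n_replicates",
                             "base_seed"))]
  if (!is.null(sc_args$weights)) sc_args$weights <- as.numeric(sc_args$weights)
  scenario <- do.call(bws_scenario, sc_args)
  ctl_keys <- intersect(names(cfg), c("iterations", "burn_in", "thin", "chains"))
  control <- if (length(ctl_keys)) do.call(bws_control, cfg[ctl_keys])
  list(scenario = scenario, control = control)
}

#' Write scenario results as CSV
#'
#' Columns mirror the usual simulation-table layout: parameter, truth, point
#' estimate (median of posterior medians), average posterior SD, average
#' bias, MSE, and 95% interval coverage. A provenance header records the
#' scenario and seed.
#'
#' @param result A [run_scenario()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(result, path) {
  stopifnot(inherits(result, "bws_scenario_result"))
  sc <- result$scenario
  header <- sprintf(
    "# n=%d theta=%g residual_sd=%g regime=%s replicates=%d failed=%d base_seed=%d",
    sc$n, sc$theta, sc$residual_sd, sc$regime, sc$n_replicates,
    result$n_failed, sc$base_seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(result$summary, con, row.names = FALSE)
  invisible(path)
}
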