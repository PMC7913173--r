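#' Diagnostic and summary plots for a fit
#'
#' `type = "trace"` shows per-chain trace plots of the sampled parameters
#' (post burn-in, post thinning); `type = "weights"` shows the posterior of
#' each mixture weight as medians with HPD bars; `type = "autocorrelation"`
#' shows the chain-averaged autocorrelation function per parameter.
#'
#' @param object A `bws_fit`.
#' @param type One of `"trace"`, `"weights"`, `"autocorrelation"`.
#' @param parameters Parameters to include (default: summed effects and
#'   weights for `"weights"`, everything otherwise).
#' @param max_lag Largest lag for the autocorrelation panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bws_fit <- function(object, type = c("trace", "weights",
                                              "autocorrelation"),
                             parameters = NULL, max_lag = 40, ...) {
  type <- match.arg(type)
  if (type == "weights") {
    s <- tidy(object)
    s <- s[s$type == "weight", ]
    return(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$median,
                                      y = stats::reorder(.data$term, .data$median))) +
        ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_lower,
                                              xmax = .data$hpd_upper)) +
        ggplot2::labs(x = "Posterior median (95% HPD)", y = NULL,
                      title = "Mixture weights") +
        ggplot2::xlim(0, 1))
  }
  pars <- parameters %||% object$terms
  if (type == "trace") {
    long <- tidyr::pivot_longer(object$draws, dplyr::all_of(pars),
                                names_to = "parameter")
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$.iteration, .data$value,
                                         color = factor(.data$.chain))) +
        ggplot2::geom_line(linewidth = 0.2) +
        ggplot2::facet_wrap(~parameter, scales = "free_y") +
        ggplot2::labs(x = "Retained iteration", y = NULL, color = "Chain"))
  }
  acfs <- purrr::map_dfr(pars, function(p)
    tibble::tibble(parameter = p, lag = 0:max_lag,
                   acf = autocorrelation(object, p, max_lag)))
  ggplot2::ggplot(acfs, ggplot2::aes(.data$lag, .data$acf)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "Lag", y = "Autocorrelation")
}

#' Recovery plot for a scenario result
#'
#' Point estimates (median of posterior medians) with a reference line at the
#' truth, per parameter.
#'
#' @param object A `bws_scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bws_scenario_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(ggplot2::aes(y = .data$truth), shape = 4, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimate (x marks the truth)")
}
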