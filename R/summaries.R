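#' Highest posterior density interval
#'
#' The shortest contiguous interval containing the requested posterior mass,
#' computed from draws by the sorted-window algorithm: among all windows of
#' `ceiling(mass * n)` consecutive sorted draws, the narrowest is returned
#' (ties broken toward the lower window). For symmetric posteriors this agrees
#' with the equal-tailed interval; for skewed posteriors it is strictly
#' shorter and shifts toward the mode.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass to cover, in (0, 1); default 0.95.
#' @return A tibble with columns `lower`, `upper`, `mass`.
#' @examples
#' hpd_interval(rexp(1000), 0.9)
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (length(draws) < 100)
    abort("Need at least 100 draws for a stable HPD interval.")
  if (mass <= 0 || mass >= 1) abort("`mass` must be strictly between 0 and 1.")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(tibble::tibble(lower = x[1], upper = x[n], mass = mass))
  i <- which.min(x[m:n] - x[seq_len(n - m + 1)])
  tibble::tibble(lower = x[i], upper = x[i + m - 1], mass = mass)
}

summarize_draw_vector <- function(x, mass = 0.95) {
  h <- hpd_interval(x, mass)
  tibble::tibble(median = median(x), mean = mean(x), sd = sd(x),
                 hpd_lower = h$lower, hpd_upper = h$upper)
}

term_type <- function(terms) {
  dplyr::case_when(
    terms == "(Intercept)" ~ "intercept",
    startsWith(terms, "theta_") ~ "theta",
    startsWith(terms, "w_") ~ "weight",
    terms == "sigma" ~ "sigma",
    TRUE ~ "covariate")
}

#' Posterior summaries of a fit
#'
#' Pools post-burn-in draws across chains and reports, per parameter, the
#' posterior median (the effect estimate of interest), the mean (which shows
#' that mean weights sum to 1 even though their marginals are skewed), the
#' posterior SD, and the highest-posterior-density interval. For the logistic
#' link, `exponentiate = TRUE` maps the intercept, summed effects and
#' covariate coefficients to the odds-ratio scale by exponentiating the
#' summaries and HPD endpoints (a monotone transform).
#'
#' @param x A `bws_fit` object.
#' @param mass HPD probability mass.
#' @param exponentiate Report regression coefficients as odds ratios.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `median`, `mean`, `sd`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
tidy.bws_fit <- function(x, mass = 0.95, exponentiate = FALSE, ...) {
  out <- purrr::map_dfr(x$terms, function(p)
    dplyr::mutate(summarize_draw_vector(x$draws[[p]], mass), term = p)) |>
    dplyr::mutate(type = term_type(.data$term)) |>
    dplyr::select("term", "type", "median", "mean", "sd",
                  "hpd_lower", "hpd_upper")
  if (exponentiate) {
    tr <- out$type %in% c("intercept", "theta", "covariate")
    out <- dplyr::mutate(out, dplyr::across(
      c("median", "mean", "hpd_lower", "hpd_upper"),
      ~ ifelse(tr, exp(.x), .x)))
    out$mean[tr] <- vapply(out$term[tr], function(p) mean(exp(x$draws[[p]])),
                           numeric(1))
    out$sd[tr] <- vapply(out$term[tr], function(p) sd(exp(x$draws[[p]])),
                         numeric(1))
  }
  out
}

#' @rdname tidy.bws_fit
#' @export
bws_summary <- function(x, mass = 0.95, exponentiate = FALSE, ...) {
  if (inherits(x, "bws_fit")) return(tidy(x, mass, exponentiate))
  # a draws tibble (e.g. re-read from CSV): summarize every parameter column
  stopifnot(is.data.frame(x))
  pars <- setdiff(names(x), c(".chain", ".iteration"))
  purrr::map_dfr(pars, function(p)
    dplyr::mutate(summarize_draw_vector(x[[p]], mass), term = p)) |>
    dplyr::mutate(type = term_type(.data$term)) |>
    dplyr::select("term", "type", "median", "mean", "sd",
                  "hpd_lower", "hpd_upper")
}

#' One-line fit summary
#'
#' @param x A `bws_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: sample size, numbers of exposures/covariates,
#'   link, chain count, total retained draws, and the largest split-chain
#'   Gelman-Rubin statistic across parameters (`NA` for single-chain runs).
#' @export
glance.bws_fit <- function(x, ...) {
  max_rhat <- if (x$control$chains >= 2)
    max(bws_diagnostics(x)$rhat) else NA_real_
  tibble::tibble(n = x$data$n, n_exposures = x$data$K,
                 n_covariates = x$data$P, link = x$spec$link,
                 chains = x$control$chains,
                 draws = nrow(x$draws), max_rhat = max_rhat)
}
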