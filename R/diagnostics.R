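#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain version of the between/within-chain variance ratio: each chain
#' is split in half so the statistic is also sensitive to trends within a
#' chain. Values near 1 indicate that all chains sample the same posterior
#' distribution; values above ~1.01-1.1 indicate non-convergence.
#'
#' @param fit A [bws()] fit (needs at least 2 chains).
#' @param parameter Parameter name; see `fit$terms`.
#' @return A single numeric value, `>= 1` up to floating-point error.
#' @export
gelman_rubin <- function(fit, parameter) {
  m <- draws_matrix(fit, parameter)
  if (ncol(m) < 2)
    abort("Gelman-Rubin needs >= 2 chains; rerun with `bws_control(chains = 3)`.")
  if (nrow(m) < 10)
    abort("Chains too short for a meaningful diagnostic (need >= 10 draws).")
  half <- nrow(m) %/% 2
  splits <- cbind(m[seq_len(half), , drop = FALSE],
                  m[(nrow(m) - half + 1):nrow(m), , drop = FALSE])
  psrf(splits)
}

# potential scale reduction from an iterations x chains matrix
psrf <- function(splits) {
  L <- nrow(splits)
  W <- mean(apply(splits, 2, var))
  B <- L * var(colMeans(splits))
  if (W == 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Convergence diagnostics for every parameter
#'
#' @param fit A [bws()] fit.
#' @return A tibble with one row per parameter: the split-chain Gelman-Rubin
#'   statistic and the lag-1 autocorrelation averaged over chains.
#' @export
bws_diagnostics <- function(fit) {
  tibble::tibble(
    parameter = fit$terms,
    rhat = vapply(fit$terms, function(p) gelman_rubin(fit, p), numeric(1)),
    lag1_acf = vapply(fit$terms, function(p) {
      a <- try(autocorrelation(fit, p, max_lag = 1), silent = TRUE)
      if (inherits(a, "try-error")) NA_real_ else a[2]
    }, numeric(1)))
}

#' Chain autocorrelation function
#'
#' Normalized autocorrelation of a parameter's chain, averaged across chains;
#' lag 0 is identically 1. Slowly decaying autocorrelation signals poor mixing
#' and a small effective sample size.
#'
#' @param fit A [bws()] fit.
#' @param parameter Parameter name.
#' @param max_lag Largest lag to report; must be smaller than the chain length.
#' @return Numeric vector of length `max_lag + 1` (lags `0:max_lag`).
#' @export
autocorrelation <- function(fit, parameter, max_lag = 40) {
  m <- draws_matrix(fit, parameter)
  if (max_lag >= nrow(m)) abort("`max_lag` must be below the chain length.")
  if (any(apply(m, 2, sd) == 0))
    abort("Constant chain: autocorrelation undefined (zero variance).")
  ac <- apply(m, 2, function(x)
    drop(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf))
  rowMeans(ac)
}
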