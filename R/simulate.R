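#' Exposure correlation matrices for the simulation harness
#'
#' Two built-in regimes: `"low-moderate"` assigns off-diagonal correlations
#' cycling through 0.1, 0.2, 0.3, 0.4, 0.5 by pair index (row-wise over the
#' upper triangle), a fixed deterministic matrix spanning the low-to-moderate
#' range; `"high"` is exchangeable with all off-diagonals 0.9. Both are
#' positive definite for K = 5 (minimum eigenvalues 0.44 and 0.1).
#'
#' @param regime `"low-moderate"`, `"high"`, or a K x K correlation matrix
#'   passed through unchanged (validated).
#' @param k Number of exposures.
#' @return A K x K positive-definite correlation matrix.
#' @export
correlation_matrix <- function(regime = c("low-moderate", "high"), k = 5) {
  if (is.matrix(regime)) {
    if (nrow(regime) != ncol(regime) || any(abs(diag(regime) - 1) > 1e-12))
      abort("A custom correlation matrix must be square with unit diagonal.")
    if (min(eigen(regime, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      abort("Correlation matrix is not positive definite.")
    return(regime)
  }
  regime <- match.arg(regime)
  R <- diag(k)
  if (regime == "high") {
    R[upper.tri(R)] <- R[lower.tri(R)] <- 0.9
  } else {
    vals <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), length.out = k * (k - 1) / 2)
    idx <- 1
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      R[i, j] <- R[j, i] <- vals[idx]
      idx <- idx + 1
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    abort("Constructed correlation matrix is not positive definite.")
  R
}

#' Define a simulation scenario
#'
#' One cell of the Monte-Carlo recovery study: a sample size, a true summed
#' effect and weight vector, an exposure correlation regime, a residual SD and
#' a replicate count. Exposures are drawn multivariate normal with mean 0,
#' unit variances and the scenario correlation; the Gaussian outcome is
#' `y = theta * sum_k w_k x_k + e`, `e ~ N(0, residual_sd^2)` with intercept
#' 0; the logistic option draws a Bernoulli outcome from the analogous linear
#' predictor.
#'
#' @param n Observations per replicate dataset.
#' @param theta True summed mixture effect.
#' @param weights True simplex weight vector (its length sets the number of
#'   exposures).
#' @param correlation `"low-moderate"`, `"high"`, or an explicit correlation
#'   matrix (see [correlation_matrix()]).
#' @param residual_sd Residual SD of the Gaussian outcome model.
#' @param link `"gaussian"` or `"logit"`.
#' @param n_replicates Monte-Carlo replicates.
#' @param base_seed Seed base; replicate `r` uses `base_seed + r` for data
#'   generation, so the whole scenario is reproducible.
#' @return An object of class `bws_scenario`.
#' @examples
#' bws_scenario(n = 250, theta = 1, residual_sd = 0.5)
#' @export
bws_scenario <- function(n = 250, theta = 1.0,
                         weights = c(0.1, 0.3, 0.2, 0.1, 0.3),
                         correlation = "low-moderate",
                         residual_sd = 0.5,
                         link = c("gaussian", "logit"),
                         n_replicates = 150, base_seed = 1) {
  link <- match.arg(link)
  check_simplex(weights, "true weights")
  R <- correlation_matrix(correlation, k = length(weights))
  structure(
    list(n = as.integer(n), theta = theta, weights = weights,
         correlation = R,
         regime = if (is.character(correlation)) correlation else "custom",
         residual_sd = residual_sd, link = link,
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed)),
    class = "bws_scenario")
}

#' Draw one replicate dataset from a scenario
#'
#' Deterministic given `(scenario$base_seed, replicate)`: the replicate index
#' selects an RNG substream, so replicates are reproducible individually and
#' independent of evaluation order.
#'
#' @param scenario A [bws_scenario()].
#' @param replicate Replicate index (1-based).
#' @return A tibble with outcome column `y` and exposure columns `x1..xK`.
#' @export
simulate_mixture <- function(scenario, replicate = 1) {
  stopifnot(inherits(scenario, "bws_scenario"), replicate >= 1)
  k <- length(scenario$weights)
  seed_r <- scenario$base_seed + as.integer(replicate)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_r)
  Zraw <- matrix(rnorm(scenario$n * k), scenario$n, k)
  X <- Zraw %*% chol(scenario$correlation)
  eta <- drop(X %*% scenario$weights) * scenario$theta
  y <- if (scenario$link == "gaussian") {
    eta + rnorm(scenario$n, 0, scenario$residual_sd)
  } else {
    rbinom(scenario$n, 1, 1 / (1 + exp(-eta)))
  }
  colnames(X) <- paste0("x", seq_len(k))
  dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
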