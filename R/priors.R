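#' Prior specification for a Bayesian weighted-sums model
#'
#' Collects the prior hyperparameters of the model. The summed-effect
#' coefficients receive independent normal priors, by default the very weakly
#' informative N(0, 100); the intercept and any covariate coefficients default
#' to the same choice. Each group's weight vector receives a Dirichlet prior,
#' by default Dirichlet(1, ..., 1), i.e. uniform on the simplex, which encodes
#' that a priori all exposures contribute equally. For the Gaussian link the
#' residual standard deviation needs a prior: the default is a half-Cauchy on
#' the SD scale; an inverse-gamma on the variance is available for
#' comparability with classic BUGS/JAGS formulations.
#'
#' @param theta_mean,theta_var Normal prior mean and variance for each summed
#'   effect coefficient.
#' @param intercept_mean,intercept_var Normal prior mean and variance for the
#'   intercept.
#' @param coef_mean,coef_var Normal prior mean and variance for covariate
#'   coefficients.
#' @param dirichlet_alpha Dirichlet concentration for the weights: a single
#'   positive number recycled across a group's exposures, or a named list of
#'   vectors (one per exposure group).
#' @param sigma_prior Prior family for the Gaussian residual SD:
#'   `"half-cauchy"` (on the SD) or `"inv-gamma"` (on the variance).
#' @param sigma_scale Scale of the half-Cauchy prior.
#' @param ig_shape,ig_rate Shape and rate of the inverse-gamma prior on the
#'   residual variance.
#'
#' @return An object of class `bws_priors`.
#' @examples
#' bws_priors()
#' bws_priors(dirichlet_alpha = 2, sigma_prior = "inv-gamma")
#' @export
bws_priors <- function(theta_mean = 0, theta_var = 100,
                       intercept_mean = 0, intercept_var = 100,
                       coef_mean = 0, coef_var = 100,
                       dirichlet_alpha = 1,
                       sigma_prior = c("half-cauchy", "inv-gamma"),
                       sigma_scale = 2.5,
                       ig_shape = 0.01, ig_rate = 0.01) {
  sigma_prior <- match.arg(sigma_prior)
  stopifnot(theta_var > 0, intercept_var > 0, coef_var > 0,
            sigma_scale > 0, ig_shape > 0, ig_rate > 0)
  if (is.numeric(dirichlet_alpha) && any(dirichlet_alpha <= 0))
    abort("`dirichlet_alpha` must be positive.")
  structure(
    list(theta_mean = theta_mean, theta_var = theta_var,
         intercept_mean = intercept_mean, intercept_var = intercept_var,
         coef_mean = coef_mean, coef_var = coef_var,
         dirichlet_alpha = dirichlet_alpha,
         sigma_prior = sigma_prior, sigma_scale = sigma_scale,
         ig_shape = ig_shape, ig_rate = ig_rate),
    class = "bws_priors")
}

#' Sampler configuration
#'
#' MCMC run-length settings. The defaults mirror a standard production run:
#' 30,000 iterations with a 3,000-iteration burn-in, thinning of 2, and three
#' chains for convergence diagnostics. Each retained chain therefore holds
#' `(iterations - burn_in) / thin` draws.
#'
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain. Proposal
#'   step sizes adapt only during burn-in and are frozen afterwards.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param chains Number of independent chains.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. `NULL` leaves the
#'   RNG state untouched (runs are then not reproducible).
#'
#' @return An object of class `bws_control`.
#' @examples
#' bws_control(iterations = 6000, burn_in = 1000, chains = 1, seed = 7)
#' @export
bws_control <- function(iterations = 30000, burn_in = 3000, thin = 2,
                        chains = 3, seed = NULL) {
  stopifnot(iterations > 0, burn_in >= 0, burn_in < iterations,
            thin >= 1, chains >= 1)
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), chains = as.integer(chains),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "bws_control")
}
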