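#' Weighted sum of a group of exposure columns
#'
#' Computes the mixture index `sum_k w_k * X[, idx_k]`, the quantity whose
#' regression coefficient is the summed mixture effect. The weights must lie
#' on the unit simplex so the index is a convex combination of the exposures.
#'
#' @param exposures Numeric matrix (or data frame) of exposures, observations
#'   in rows.
#' @param weights Simplex vector: nonnegative, summing to 1 within `1e-8`.
#' @param members Column indices (or names) of the group's exposures; defaults
#'   to all columns in order.
#' @param group Group label used in error messages.
#'
#' @return Numeric vector of length `nrow(exposures)`.
#' @examples
#' X <- matrix(c(1, 3, 2, 4), nrow = 2)
#' bws_weighted_sum(X, c(0.25, 0.75))
#' @export
bws_weighted_sum <- function(exposures, weights, members = NULL, group = "mixture") {
  X <- as.matrix(exposures)
  if (is.null(members)) members <- seq_len(ncol(X))
  if (length(weights) != length(members))
    abort(sprintf(
      "Group '%s': %d weights supplied but %d member exposures expected.",
      group, length(weights), length(members)))
  check_simplex(weights, group)
  drop(X[, members, drop = FALSE] %*% weights)
}

check_simplex <- function(w, group = "mixture", tol = 1e-8) {
  if (any(w < 0) || abs(sum(w) - 1) > tol)
    abort(sprintf(
      "Group '%s': weights must be nonnegative and sum to 1 (got sum %.10f).",
      group, sum(w)))
  invisible(w)
}

# Internal model specification: link, exposure groups (1-based indices into
# the exposure matrix), covariate count, priors.
bws_spec <- function(link = c("gaussian", "logit"), groups, n_covariates = 0,
                     priors = bws_priors()) {
  link <- match.arg(link)
  stopifnot(length(groups) >= 1)
  all_idx <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_idx))
    abort("Exposure groups must be pairwise disjoint.")
  groups <- lapply(groups, function(g) {
    stopifnot(length(g$members) >= 1, !anyDuplicated(g$members))
    if (is.null(g$alpha)) {
      a <- priors$dirichlet_alpha
      g$alpha <- if (is.list(a)) a[[g$name]] else rep(a, length(g$members))
    }
    if (length(g$alpha) != length(g$members) || any(g$alpha <= 0))
      abort(sprintf("Group '%s': needs %d positive Dirichlet alphas.",
                    g$name, length(g$members)))
    g
  })
  structure(list(link = link, groups = groups,
                 n_covariates = as.integer(n_covariates), priors = priors),
            class = "bws_spec")
}

# Parameter state constructor with invariant checks.
bws_state <- function(intercept, theta, weights, coefs = numeric(0),
                      sigma = NULL, spec = NULL) {
  stopifnot(is.numeric(theta), is.list(weights))
  for (w in weights) check_simplex(w, tol = 1e-8)
  if (!is.null(sigma) && sigma <= 0) abort("`sigma` must be positive.")
  st <- list(intercept = intercept, theta = theta, weights = weights,
             coefs = coefs, sigma = sigma)
  if (!is.null(spec)) {
    stopifnot(length(theta) == length(spec$groups),
              length(coefs) == spec$n_covariates)
    if (spec$link == "gaussian" && is.null(sigma))
      abort("Gaussian link requires `sigma` in the state.")
  }
  st
}

linear_predictor <- function(state, data, spec) {
  eta <- rep(state$intercept, length(data$y))
  for (g in seq_along(spec$groups)) {
    grp <- spec$groups[[g]]
    eta <- eta + state$theta[g] *
      bws_weighted_sum(data$X, state$weights[[g]], grp$members, grp$name)
  }
  if (spec$n_covariates > 0)
    eta <- eta + drop(data$Z %*% state$coefs)
  if (any(!is.finite(eta)))
    abort(sprintf("Non-finite linear predictor at row %d.",
                  which(!is.finite(eta))[1]))
  eta
}

#' Model log-likelihood
#'
#' Evaluates the log-likelihood of a parameter state: a sum of normal
#' densities around the linear predictor for the Gaussian link, or of
#' Bernoulli log-masses under the logistic link. The logistic term uses a
#' guarded `log(1 + exp(eta))` so it stays finite for any finite predictor.
#'
#' @param state Parameter state: a list with `intercept`, `theta` (one value
#'   per group), `weights` (list of simplex vectors), `coefs`, and `sigma`
#'   (Gaussian link only).
#' @param data List with outcome `y`, exposure matrix `X`, covariate matrix
#'   `Z` (see [bws()] which assembles it from a data frame).
#' @param spec Model specification as built by [bws()] (available as
#'   `fit$spec`).
#'
#' @return A single numeric value.
#' @seealso [bws_log_prior()], [bws_log_posterior()]
#' @export
bws_log_likelihood <- function(state, data, spec) {
  eta <- linear_predictor(state, data, spec)
  if (spec$link == "gaussian") {
    sum(dnorm(data$y, mean = eta, sd = state$sigma, log = TRUE))
  } else {
    sum(data$y * eta - log1p_exp(eta))
  }
}

log1p_exp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37; hi <- x > 18; mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  big <- hi & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out[hi & x > 33.3] <- x[hi & x > 33.3]
  out
}

ldirichlet <- function(w, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(w))
}

#' Joint log-prior of a parameter state
#'
#' Sums the normal log-densities of the intercept, summed-effect and covariate
#' coefficients, the Dirichlet log-density of each group's weight vector, and
#' (Gaussian link) the residual-SD prior term. Weights of single-exposure
#' groups are degenerate at 1 and contribute nothing.
#'
#' @inheritParams bws_log_likelihood
#' @return A single numeric value.
#' @export
bws_log_prior <- function(state, spec) {
  pr <- spec$priors
  lp <- dnorm(state$intercept, pr$intercept_mean, sqrt(pr$intercept_var), log = TRUE)
  for (g in seq_along(spec$groups)) {
    lp <- lp + dnorm(state$theta[g], pr$theta_mean, sqrt(pr$theta_var), log = TRUE)
    w <- state$weights[[g]]
    check_simplex(w, spec$groups[[g]]$name, tol = 1e-8)
    if (length(w) > 1) lp <- lp + ldirichlet(w, spec$groups[[g]]$alpha)
  }
  if (spec$n_covariates > 0)
    lp <- lp + sum(dnorm(state$coefs, pr$coef_mean, sqrt(pr$coef_var), log = TRUE))
  if (spec$link == "gaussian") {
    lp <- lp + if (pr$sigma_prior == "half-cauchy") {
      log(2) - log(pi * pr$sigma_scale * (1 + (state$sigma / pr$sigma_scale)^2))
    } else {
      s2 <- state$sigma^2
      pr$ig_shape * log(pr$ig_rate) - lgamma(pr$ig_shape) -
        (pr$ig_shape + 1) * log(s2) - pr$ig_rate / s2
    }
  }
  lp
}

#' Joint log-posterior (up to the marginal-likelihood constant)
#'
#' The sampler's target: `bws_log_likelihood() + bws_log_prior()`.
#'
#' @inheritParams bws_log_likelihood
#' @return A single numeric value.
#' @export
bws_log_posterior <- function(state, data, spec) {
  bws_log_likelihood(state, data, spec) + bws_log_prior(state, spec)
}
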