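# shared test utilities: tiny fixtures, independent oracles

# minimal bws_fit-shaped object from a list of per-chain draw vectors,
# for exercising diagnostics without running the sampler
make_fake_fit <- function(chains, name = "x") {
  draws <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    d <- tibble::tibble(.chain = ch, .iteration = seq_along(chains[[ch]]),
                        value = as.numeric(chains[[ch]]))
    names(d)[3] <- name
    d
  }))
  structure(list(draws = draws, terms = name), class = "bws_fit")
}

# brute-force HPD: scan every contiguous window of ceiling(mass * n) sorted
# draws; independent of the package's sorted-window implementation
brute_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1)]
  best <- which.min(widths)
  c(lower = x[best], upper = x[best + m - 1])
}

# closed-form posterior for the Gaussian model with fixed weights and fixed
# residual SD: conjugate normal in the regression coefficients
conjugate_posterior <- function(y, A, sigma, prior_var = 100) {
  V <- solve(crossprod(A) / sigma^2 + diag(1 / prior_var, ncol(A)))
  list(mean = drop(V %*% (crossprod(A, y) / sigma^2)), var = V)
}

# Monte-Carlo standard error from autocorrelation-adjusted effective size
mcse <- function(x) {
  ess <- tryCatch(as.numeric(coda::effectiveSize(x)), error = function(e) NA)
  if (!is.finite(ess) || ess < 1) ess <- length(x) / 20
  sd(x) / sqrt(ess)
}

tiny_control <- function(seed = 1, chains = 1)
  bws_control(iterations = 3000, burn_in = 500, thin = 1,
              chains = chains, seed = seed)

# small deterministic regression dataset
tiny_data <- function(n = 60, k = 3, seed = 42, theta = 1,
                      w = rep(1 / k, k), sd = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n, k)
    y <- theta * drop(X %*% w) + rnorm(n, 0, sd)
    colnames(X) <- paste0("x", seq_len(k))
    dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
  })
}

# direct state/data/spec builders for the model-core functions
core_objects <- function(d, k = 3, link = "gaussian",
                         priors = bws_priors()) {
  X <- as.matrix(d[, paste0("x", seq_len(k))])
  data <- list(y = d$y, X = X, Z = matrix(0, nrow(d), 0))
  spec <- bwsreg:::bws_spec(link,
                            list(list(name = "mixture", members = seq_len(k))),
                            n_covariates = 0, priors = priors)
  list(data = data, spec = spec)
}
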