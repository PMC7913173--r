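test_that("weighted sum is the stated convex combination", {
  # identity and symmetry cases
  x <- matrix(c(2, 5, 9), ncol = 1)
  expect_equal(bws_weighted_sum(x, 1), c(2, 5, 9))
  Xc <- matrix(3, nrow = 4, ncol = 5)
  expect_equal(bws_weighted_sum(Xc, rep(0.2, 5)), rep(3, 4))
  # hand arithmetic
  X <- matrix(c(1, 3, 2, 4), nrow = 2)  # rows (1,2), (3,4)
  expect_equal(bws_weighted_sum(X, c(0.25, 0.75)), c(1.75, 3.75))
  # dimension mismatch names the group and expected length
  expect_error(bws_weighted_sum(X, c(0.5, 0.25, 0.25), group = "pbde"),
               "pbde.*3 weights.*2 member")
  expect_error(bws_weighted_sum(X, c(0.6, 0.6)), "sum to 1")
})

test_that("log-likelihood matches per-observation density sums", {
  # zero-residual Gaussian case
  co <- core_objects(tiny_data(n = 1, k = 3, sd = 0), k = 3)
  st <- bwsreg:::bws_state(0, 1, list(rep(1 / 3, 3)), sigma = 1)
  expect_equal(bws_log_likelihood(st, co$data, co$spec),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # brute-force oracle on a fixed dataset, interior state
  d <- tiny_data(n = 25, k = 3, seed = 7)
  co <- core_objects(d, k = 3)
  st <- bwsreg:::bws_state(0.3, 0.8, list(c(0.2, 0.5, 0.3)), sigma = 0.7)
  eta <- 0.3 + 0.8 * as.matrix(d[, 2:4]) %*% c(0.2, 0.5, 0.3)
  oracle <- sum(vapply(seq_len(25), function(i)
    dnorm(d$y[i], eta[i], 0.7, log = TRUE), numeric(1)))
  expect_equal(bws_log_likelihood(st, co$data, co$spec), oracle,
               tolerance = 1e-10)

  # symmetric logistic case: eta = 0 gives n * log(1/2)
  d$y <- rep(c(0, 1), length.out = 25)
  co <- core_objects(d, k = 3, link = "logit")
  st0 <- bwsreg:::bws_state(0, 0, list(c(0.2, 0.5, 0.3)))
  expect_equal(bws_log_likelihood(st0, co$data, co$spec), 25 * log(0.5),
               tolerance = 1e-12)
  # and the guarded log1p(exp()) stays finite at extreme predictors
  st_big <- bwsreg:::bws_state(500, 0, list(c(0.2, 0.5, 0.3)))
  expect_true(is.finite(bws_log_likelihood(st_big, co$data, co$spec)))
})

test_that("log-prior combines normal, Dirichlet and residual-SD terms", {
  co <- core_objects(tiny_data(n = 20, k = 4), k = 4)
  pr <- co$spec$priors
  # flat Dirichlet(1,..,1) contributes the constant log Gamma(K) anywhere
  st1 <- bwsreg:::bws_state(0.5, 2, list(c(0.4, 0.3, 0.2, 0.1)), sigma = 1)
  st2 <- bwsreg:::bws_state(0.5, 2, list(rep(0.25, 4)), sigma = 1)
  expect_equal(bws_log_prior(st1, co$spec), bws_log_prior(st2, co$spec),
               tolerance = 1e-12)
  # theta at the prior mode under N(0, 100), other terms stripped off
  base <- bws_log_prior(bwsreg:::bws_state(0, 0, list(rep(0.25, 4)), sigma = 1),
                        co$spec)
  shifted <- bws_log_prior(bwsreg:::bws_state(0, 3, list(rep(0.25, 4)), sigma = 1),
                           co$spec)
  expect_equal(shifted - base, dnorm(3, 0, 10, log = TRUE) -
                 (-0.5 * log(2 * pi * 100)), tolerance = 1e-12)

  # closed-form Dirichlet density, non-uniform alpha
  co3 <- core_objects(tiny_data(n = 20, k = 3), k = 3,
                      priors = bws_priors(dirichlet_alpha = 2))
  w <- c(0.2, 0.3, 0.5)
  dir_oracle <- lgamma(6) - 3 * lgamma(2) + sum((2 - 1) * log(w))
  diff <- bws_log_prior(bwsreg:::bws_state(0, 0, list(w), sigma = 1), co3$spec) -
    bws_log_prior(bwsreg:::bws_state(0, 0, list(rep(1/3, 3)), sigma = 1), co3$spec)
  dir_unif <- lgamma(6) - 3 * lgamma(2) + sum(log(rep(1/3, 3)))
  expect_equal(diff, dir_oracle - dir_unif, tolerance = 1e-12)

  # weights off the simplex are rejected
  expect_error(bws_log_prior(
    bwsreg:::bws_state(0, 0, list(c(0.5, 0.6, 0.1)), sigma = 1), co3$spec),
    "sum to 1")
})

test_that("log-posterior is likelihood plus prior and prior-exchangeable", {
  d <- tiny_data(n = 30, k = 4, seed = 9)
  co <- core_objects(d, k = 4)
  withr::with_seed(11, {
    for (i in 1:5) {
      w <- bwsreg:::rdirichlet1(rep(1, 4))
      st <- bwsreg:::bws_state(rnorm(1), rnorm(1), list(w),
                               sigma = abs(rnorm(1)) + 0.2)
      expect_equal(bws_log_posterior(st, co$data, co$spec),
                   bws_log_likelihood(st, co$data, co$spec) +
                     bws_log_prior(st, co$spec), tolerance = 1e-12)
      # permuting a group's members together with its weights changes nothing
      perm <- sample(4)
      co_p <- co
      co_p$spec$groups[[1]]$members <- co$spec$groups[[1]]$members[perm]
      st_p <- st
      st_p$weights <- list(w[perm])
      expect_equal(bws_log_posterior(st_p, co$data, co_p$spec),
                   bws_log_posterior(st, co$data, co$spec), tolerance = 1e-10)
    }
  })
})

test_that("C++ sampler target agrees with the R model evaluation", {
  d <- tiny_data(n = 40, k = 3, seed = 5)
  co <- core_objects(d, k = 3)
  pr <- co$spec$priors
  prior_pack <- c(pr$intercept_mean, pr$intercept_var, pr$theta_mean,
                  pr$theta_var, pr$coef_mean, pr$coef_var)
  sigma_pack <- c(pr$sigma_scale, pr$ig_shape, pr$ig_rate)
  withr::with_seed(3, {
    for (i in 1:5) {
      w <- bwsreg:::rdirichlet1(rep(1, 3))
      st <- bwsreg:::bws_state(rnorm(1), rnorm(1), list(w),
                               sigma = abs(rnorm(1)) + 0.2)
      cpp <- bwsreg:::cpp_log_posterior(
        co$data$y, co$data$X, co$data$Z, list(0:2), list(rep(1, 3)), 0L,
        prior_pack, 0L, sigma_pack,
        c(st$intercept, st$theta), list(w), st$sigma)
      expect_equal(cpp, bws_log_posterior(st, co$data, co$spec),
                   tolerance = 1e-10)
    }
  })
})

test_that("a single-exposure group reduces to plain regression", {
  # K_g = 1: weight degenerate at 1, log-posterior equals the ordinary
  # Bayesian simple-regression log-posterior computed directly
  d <- tiny_data(n = 30, k = 1, seed = 13, w = 1)
  co <- core_objects(d, k = 1)
  st <- bwsreg:::bws_state(0.2, 0.9, list(1), sigma = 0.6)
  eta <- 0.2 + 0.9 * d$x1
  direct <- sum(dnorm(d$y, eta, 0.6, log = TRUE)) +
    dnorm(0.2, 0, 10, log = TRUE) + dnorm(0.9, 0, 10, log = TRUE) +
    log(2) - log(pi * 2.5 * (1 + (0.6 / 2.5)^2))
  expect_equal(bws_log_posterior(st, co$data, co$spec), direct,
               tolerance = 1e-12)
})
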