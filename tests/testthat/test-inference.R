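test_that("sampling is reproducible, seed-sensitive, and bookkept exactly", {
  d <- tiny_data(n = 60, k = 3, seed = 2)
  ctl <- bws_control(iterations = 1200, burn_in = 300, thin = 3,
                     chains = 2, seed = 99)
  f1 <- bws(d, "y", paste0("x", 1:3), control = ctl)
  f2 <- bws(d, "y", paste0("x", 1:3), control = ctl)
  expect_identical(f1$draws, f2$draws)  # bit-identical rerun

  f3 <- bws(d, "y", paste0("x", 1:3),
            control = bws_control(1200, 300, 3, chains = 2, seed = 100))
  expect_false(identical(f1$draws, f3$draws))

  # output length is exactly floor((iterations - burn_in) / thin) per chain
  expect_equal(nrow(f1$draws), 2 * ((1200 - 300) %/% 3))
  expect_equal(unname(table(f1$draws$.chain)), c(300L, 300L),
               ignore_attr = TRUE)

  # chains are distinct (overdispersed inits, separate streams)
  expect_false(identical(f1$draws$theta_mixture[f1$draws$.chain == 1],
                         f1$draws$theta_mixture[f1$draws$.chain == 2]))
})

test_that("every retained weight draw lies on the simplex", {
  d <- tiny_data(n = 80, k = 4, seed = 21, w = c(0.4, 0.3, 0.2, 0.1))
  f <- bws(d, "y", paste0("x", 1:4), control = tiny_control(seed = 5))
  W <- as.matrix(f$draws[, paste0("w_mixture_x", 1:4)])
  expect_true(all(abs(rowSums(W) - 1) < 1e-10))
  expect_true(all(W > 0 & W < 1))
})

test_that("fixed-weight Gaussian model matches the conjugate closed form", {
  w_true <- c(0.2, 0.5, 0.3)
  d <- tiny_data(n = 120, k = 3, seed = 31, w = w_true, sd = 0.5)
  f <- bws(d, "y", paste0("x", 1:3),
           control = bws_control(12000, 2000, 2, chains = 1, seed = 8),
           fix_weights = list(mixture = w_true), fix_sigma = 0.5)
  A <- cbind(1, as.matrix(d[, 2:4]) %*% w_true)
  post <- conjugate_posterior(d$y, A, sigma = 0.5)
  for (j in 1:2) {
    draws <- f$draws[[c("(Intercept)", "theta_mixture")[j]]]
    tol <- 3 * mcse(draws)
    expect_lt(abs(mean(draws) - post$mean[j]), tol + 1e-8)
    expect_lt(abs(sd(draws) - sqrt(post$var[j, j])),
              3 * sd(draws) / sqrt(length(draws) / 10) + 0.002)
  }
})

test_that("single-exposure fit agrees with direct Bayesian regression", {
  # with one exposure the model is ordinary regression with coefficient theta
  withr::with_seed(17, {
    x <- rnorm(100)
    y <- 0.3 + 1.2 * x + rnorm(100, 0, 0.4)
  })
  d <- tibble::tibble(y = y, x1 = x)
  f <- bws(d, "y", "x1",
           control = bws_control(12000, 2000, 2, chains = 1, seed = 4),
           fix_sigma = 0.4)
  post <- conjugate_posterior(y, cbind(1, x), sigma = 0.4)
  th <- f$draws$theta_mixture
  expect_lt(abs(mean(th) - post$mean[2]), 3 * mcse(th) + 1e-8)
  expect_lt(abs(sd(th) - sqrt(post$var[2, 2])), 0.01)
  # the degenerate weight column is identically 1
  expect_true(all(f$draws$w_mixture_x1 == 1))
})

test_that("posterior agrees with an independent Gibbs implementation (JAGS)", {
  d <- tiny_data(n = 100, k = 3, seed = 41, w = c(0.5, 0.3, 0.2), sd = 0.5)
  pr <- bws_priors(sigma_prior = "inv-gamma", ig_shape = 0.01, ig_rate = 0.01)
  f <- bws(d, "y", paste0("x", 1:3), priors = pr,
           control = bws_control(20000, 4000, 2, chains = 1, seed = 6))

  model_str <- "
    model {
      for (i in 1:n) {
        mu[i] <- theta0 + theta * (w[1]*X[i,1] + w[2]*X[i,2] + w[3]*X[i,3])
        y[i] ~ dnorm(mu[i], tau)
      }
      theta0 ~ dnorm(0, 0.01)
      theta ~ dnorm(0, 0.01)
      w ~ ddirch(alpha)
      tau ~ dgamma(0.01, 0.01)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = d$y, X = as.matrix(d[, 2:4]), n = 100, alpha = rep(1, 3)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
    n.chains = 1, quiet = TRUE)
  update(jm, 4000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("theta", "w"), n.iter = 16000, thin = 2,
                            progress.bar = "none")[[1]]

  expect_lt(abs(mean(f$draws$theta_mixture) - mean(js[, "theta"])),
            3 * sqrt(mcse(f$draws$theta_mixture)^2 + mcse(js[, "theta"])^2) + 0.005)
  for (k in 1:3)
    expect_lt(abs(mean(f$draws[[paste0("w_mixture_x", k)]]) -
                    mean(js[, paste0("w[", k, "]")])), 0.015)
})

test_that("scale equivariance: rescaling exposures rescales theta, not weights", {
  d <- tiny_data(n = 300, k = 3, seed = 51, w = c(0.5, 0.3, 0.2), sd = 0.4)
  d2 <- dplyr::mutate(d, dplyr::across(dplyr::starts_with("x"), ~ .x * 4))
  ctl <- bws_control(8000, 1500, 2, chains = 1, seed = 12)
  f1 <- bws(d, "y", paste0("x", 1:3), control = ctl)
  f2 <- bws(d2, "y", paste0("x", 1:3), control = ctl)
  expect_lt(abs(median(f2$draws$theta_mixture) * 4 -
                  median(f1$draws$theta_mixture)), 0.03)
  for (k in 1:3)
    expect_lt(abs(median(f1$draws[[paste0("w_mixture_x", k)]]) -
                    median(f2$draws[[paste0("w_mixture_x", k)]])), 0.03)
})

test_that("Gelman-Rubin statistic behaves per its defining formula", {
  # identical chains: no between-chain variance
  x <- withr::with_seed(1, rnorm(200))
  expect_equal(gelman_rubin(make_fake_fit(list(x, x)), "x"), 1,
               tolerance = 0.005)

  # far-separated chains: direct evaluation of the split-chain formula
  a <- withr::with_seed(2, rnorm(200, 0, 1))
  b <- withr::with_seed(3, rnorm(200, 10, 1))
  got <- gelman_rubin(make_fake_fit(list(a, b)), "x")
  splits <- cbind(a[1:100], a[101:200], b[1:100], b[101:200])
  L <- 100
  W <- mean(apply(splits, 2, var))
  B <- L * var(colMeans(splits))
  expect_equal(got, sqrt(((L - 1) / L * W + B / L) / W), tolerance = 1e-12)
  expect_gt(got, 1.1)

  expect_error(gelman_rubin(make_fake_fit(list(x)), "x"), "chains")
})

test_that("well-mixed chains at production settings converge", {
  d <- tiny_data(n = 150, k = 3, seed = 61, w = c(0.5, 0.3, 0.2))
  f <- bws(d, "y", paste0("x", 1:3),
           control = bws_control(6000, 1000, 2, chains = 3, seed = 2))
  expect_true(all(bws_diagnostics(f)$rhat < 1.03))
})

test_that("autocorrelation matches sampling theory on known processes", {
  # lag 0 is identically one; white noise stays inside the 3/sqrt(L) band
  wn <- withr::with_seed(4, rnorm(2000))
  ac <- autocorrelation(make_fake_fit(list(wn)), "x", max_lag = 20)
  expect_equal(ac[1], 1)
  expect_true(all(abs(ac[-1]) < 3 / sqrt(2000)))

  # AR(1): lag-k autocorrelation decays as phi^k
  phi <- 0.8
  ar <- withr::with_seed(5,
    as.numeric(arima.sim(list(ar = phi), n = 20000)))
  ac_ar <- autocorrelation(make_fake_fit(list(ar)), "x", max_lag = 5)
  expect_equal(ac_ar[-1], phi^(1:5), tolerance = 0.08)

  expect_error(autocorrelation(make_fake_fit(list(rep(1, 50))), "x", 5),
               "zero variance")
  expect_error(autocorrelation(make_fake_fit(list(wn)), "x", 3000),
               "below the chain length")
})
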