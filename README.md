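# bwsreg

Bayesian weighted-sums regression for correlated exposure mixtures.

## The problem

Epidemiologists studying chemical mixtures — PBDE congeners in maternal
serum, metals in drinking water, phthalate metabolites — face exposures that
are strongly intercorrelated because they share sources. A regression with
every component as its own term produces unstable, sign-flipping estimates;
single-exposure models ignore co-occurrence. Often the scientifically
meaningful questions are instead: *what is the effect of the mixture as a
whole*, and *what fraction of that effect does each component contribute?*

`bwsreg` answers both with one model. For outcome $y$, exposure groups $g$,
and covariates $z$:

$$ g\{E(y_i)\} = \theta_0 + \sum_g \theta_g \sum_{k=1}^{K_g} w_{gk} x_{gki} + \gamma' z_i,
\qquad w_g \sim \mathrm{Dirichlet}(\alpha_g) $$

with identity (Gaussian) or logit (Bernoulli) link. The Dirichlet prior
constrains each group's weights to be positive and sum to 1, so $\theta_g$
is the summed mixture effect per 1-unit increase in the weighted sum, and
$w_{gk}$ is component $k$'s percent contribution. Default priors are
Dirichlet(1, …, 1) on weights, $N(0, 100)$ on $\theta_0$, $\theta_g$ and
$\gamma$, and half-Cauchy(2.5) on the Gaussian residual SD. Inference is by
an adaptive Metropolis-within-Gibbs sampler (C++ core) operating on
unconstrained log-ratio coordinates for the weights, with Gelman–Rubin and
autocorrelation diagnostics, highest-posterior-density intervals, and a
Monte-Carlo simulation harness measuring bias, MSE, average posterior SD and
interval coverage.

## Worked example

Simulate one dataset (n = 250, five exposures with low-to-moderate
correlation, true summed effect θ = 1 with weights 0.1/0.3/0.2/0.1/0.3,
residual SD 0.5) and fit at production settings:

```r
library(bwsreg)

sc  <- bws_scenario(n = 250, theta = 1, residual_sd = 0.5, base_seed = 1)
d   <- simulate_mixture(sc, 1)
fit <- bws(d, "y", paste0("x", 1:5),
           control = bws_control(30000, 3000, thin = 2, chains = 3, seed = 11))
tidy(fit)
#> # A tibble: 8 × 7
#>   term          type      median   mean     sd hpd_lower hpd_upper
#>   <chr>         <chr>      <dbl>  <dbl>  <dbl>     <dbl>     <dbl>
#> 1 (Intercept)   intercept 0.0155 0.0155 0.0316 -0.0447      0.0790
#> 2 theta_mixture theta     1.02   1.02   0.0476  0.922       1.11
#> 3 w_mixture_x1  weight    0.0681 0.0685 0.0292  0.00862     0.122
#> 4 w_mixture_x2  weight    0.303  0.303  0.0315  0.240       0.364
#> 5 w_mixture_x3  weight    0.218  0.218  0.0382  0.142       0.293
#> 6 w_mixture_x4  weight    0.0436 0.0473 0.0295  0.000811    0.103
#> 7 w_mixture_x5  weight    0.363  0.363  0.0403  0.284       0.442
#> 8 sigma         sigma     0.490  0.491  0.0224  0.448       0.535
```

The summed effect is recovered (posterior median 1.02, 95% HPD 0.92–1.11
around the true 1.0), the weight medians track their truths within posterior
uncertainty, the mean weights sum to 1, and the residual SD posterior sits
on the generating value 0.5. `glance(fit)` reports the largest split-chain
Gelman–Rubin statistic across parameters (1.00 here — all three chains agree);
`autoplot(fit, "trace")` and `autoplot(fit, "weights")` plot diagnostics and
weight posteriors.

For real cohort-style data, `make_earli_like_cohort()` generates a fully
synthetic biomarker study (log-normal correlated congeners, below-LOD flags,
continuous and binary outcomes, confounders) and `bws_preprocess()` applies
LOD/√2 substitution → log transform → z-scoring in that recorded order. A
thin command-line front end over the same functions ships at
`system.file("cli", "bws-cli.R", package = "bwsreg")` with `fit`,
`simulate`, `summarize` and `make-fixture` subcommands.

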