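# hierlogit

Bayesian hierarchical (varying-intercept) logistic regression, sampled
with a self-contained No-U-Turn Hamiltonian Monte Carlo implementation,
for grouped survey data with a binary outcome.

The motivating analysis is a school-based youth tobacco survey: for
each adolescent smoker, does the respondent intend to quit smoking?
Respondents come from school grades 7–9, and grade membership plausibly
shifts the baseline odds, so the model lets the intercept vary by grade
with partial pooling:

    y_ij ~ Bernoulli(pi_ij)
    logit(pi_ij) = alpha_0j + sum_k beta_k x_ik
    alpha_0j     = alpha_0 + mu_j,   mu_j ~ N(0, sigma_mu^2)

    beta_k ~ N(0, 10),  alpha_0 ~ N(0, 10),  sigma_mu ~ half-Cauchy(0, 2.5)

(prior scales are standard deviations). Inference is by HMC/NUTS — two
chains of 4000 transitions with 2500 warmup by default — gated on the
Gelman–Rubin statistic (< 1.10 for every parameter), with Geweke
z-scores and effective sample sizes attached, a prior-informativeness
check (posterior SD < 10% of prior SD), and reporting as odds ratios
`exp(E[beta])` with equal-tailed 95% credible intervals and percentage
effects `(OR - 1) x 100`.

Because the original survey micro-data are not redistributable, the
package includes a synthetic-data generator that emulates the published
sample: 640 respondents, grade shares 0.398/0.325/0.277, some forty
binary/ordinal covariates at their published marginal means, the
published odds ratios as generating effect sizes, and an intercept
auto-calibrated so the simulated outcome prevalence matches the
published 63.3%. Everything — sampler, diagnostics, reporting — is
exercised against that generator and against independent oracles
(dense grid quadrature, finite differences, closed-form diagnostics).

## Worked example

```r
library(hierlogit)

# three-covariate synthetic survey, known truth
sim <- generate_dataset(recovery_generator_config(N = 400, seed = 42))
sim$truth$beta
#> 0.405 -0.357 0.693          # generating log odds ratios

fit <- run_chains(hl_model(sim$data),
                  sampler_config(n_iterations = 1500, n_warmup = 750,
                                 seed = 42))
render_report(odds_ratio_table(fit), check_convergence(fit))
#> Convergence gate (split R-hat < 1.1): PASS (max R-hat 1.0080)
#> parameter,odds_ratio,or_sd,ci_low,ci_high,pct_effect,significant
#> x1,1.4428,0.3410,0.9470,2.2709,44.2779,FALSE
#> x2,0.7805,0.1837,0.4853,1.1931,-21.9507,FALSE
#> x3,2.4157,0.5961,1.5467,3.8055,141.5658,TRUE
```

The fit passed the convergence gate with maximum split R-hat 1.008.
Each row is one covariate: the posterior odds ratio (truths were 1.5,
0.7, 2.0), the SD of the exponentiated draws, the equal-tailed 95%
credible bounds, the percent change in the odds of intending to quit,
and whether the interval excludes 1. At N = 400 only the strongest
effect (OR 2.0) is resolved as significant; the true values sit inside
all three intervals.

The full-scale protocol run is the same code at the defaults:

```r
sim <- generate_dataset(generator_config(seed = 1))   # N = 640, 39 covariates
fit <- run_chains(hl_model(sim$data), sampler_config(seed = 1))  # ~3 min
```

A command-line wrapper with `simulate` / `fit` / `recover` subcommands
lives at `inst/cli/hierlogit.R` (see `?hl_main` for flags and exit
codes).

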