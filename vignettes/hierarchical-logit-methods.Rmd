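---
title: "Methods: varying-intercept Bayesian logistic regression with NUTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: varying-intercept Bayesian logistic regression with NUTS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hierlogit` fits a Bayesian logistic regression for a binary survey
outcome — the motivating application is whether an adolescent smoker
intends to quit smoking — in which the intercept varies across a small
number of groups (school grades 7, 8 and 9). For respondent $i$ in
grade $j$ with covariates $x_i \in \mathbb{R}^K$:

$$
y_{ij} \sim \mathrm{Bernoulli}(\pi_{ij}), \qquad
\mathrm{logit}(\pi_{ij}) = \alpha_{0j} + \sum_k \beta_k x_{ik}, \qquad
\alpha_{0j} = \alpha_0 + \mu_j,
$$

with priors

$$
\beta_k \sim N(0, 10^2), \quad \alpha_0 \sim N(0, 10^2), \quad
\mu_j \sim N(0, \sigma_\mu^2), \quad
\sigma_\mu \sim \mathrm{Cauchy}^+(0, 2.5).
$$

Scales are standard deviations, the convention of the mainstream
Bayesian estimation stacks; the Cauchy prior on the group scale is
half-Cauchy, the standard weakly informative choice for a scale
parameter. The hierarchy partially pools the three grade intercepts
toward a common mean, so a grade's intercept is not estimated from its
rows alone.

Two reparameterizations are applied before sampling, both invisible in
the reported posterior:

* **Non-centered group effects.** We sample standardized deviations
  $\tilde\mu_j \sim N(0,1)$ and set $\mu_j = \sigma_\mu \tilde\mu_j$.
  With only $J = 3$ groups the joint posterior of
  $(\mu_j, \sigma_\mu)$ in centered form has a funnel geometry that
  defeats fixed-step-size integrators; the non-centered form induces
  exactly the same posterior on $\alpha_{0j}$.
* **Unconstrained scale.** $\sigma_\mu$ is carried as
  $\log \sigma_\mu$ with the log-Jacobian added to the target density,
  which is required for correct Hamiltonian dynamics on a constrained
  parameter.

The Bernoulli log-likelihood is evaluated directly from the logits as
$\sum_i y_i\eta_i - \log(1 + e^{\eta_i})$ with a `log1p`-style guard,
so it stays finite for any finite parameter value; probabilities are
never formed in the density or its gradient.

## Sampling

Posterior draws come from Hamiltonian Monte Carlo with the No-U-Turn
trajectory criterion, implemented in the package (leapfrog integrator,
slice-variant tree doubling with the momentum/position-difference
U-turn test, divergence flagged at an energy error of 1000, tree depth
capped at 10). We chose the slice formulation of the candidate-leaf
selection — the original formulation of the algorithm — rather than
multinomial weighting; either satisfies the sampler's contracts and
the choice is recorded here.

**Adaptation.** Step size follows dual averaging toward a target
acceptance statistic; the diagonal mass matrix is estimated from the
draw variances of the third quarter of warmup (draws in
$(0.5, 0.75]$ of the warmup span), slightly regularized, after which
dual averaging re-opens so the step size re-adapts to the new metric
and freezes at the warmup boundary. Restricting mass estimation to a
post-transient window keeps early, far-from-typical-set draws out of
the metric. On warmups shorter than 80 iterations mass adaptation is
skipped (too few draws to estimate variances usefully).

**Defaults.** Two chains of 4000 transitions with 2500 discarded as
warmup — the survey protocol this package replicates — with chains
initialized at independent uniform$(-1, 1)$ unconstrained values and
per-chain seeds derived deterministically from the run seed, so a run
is bit-for-bit reproducible. The acceptance target defaults to 0.9: at
0.8 the reference synthetic fit (below) showed a divergent-transition
rate of several percent in one chain, while at 0.9 divergences are at
the per-mille level and the maximum split $\widehat R$ reaches the
1.003–1.004 range; the extra cost is about 30% more gradient
evaluations. A run in which any chain exceeds 10% divergent
transitions after warmup is marked failed and the reporting layer
refuses to summarize it.

## Convergence and reporting gates

`check_convergence()` computes the Gelman–Rubin statistic per
parameter, by default on split chains (each chain halved), which also
detects within-chain drift; the original unsplit formulation is
available with `split = FALSE`. No rank-normalization is applied, to
stay close to the classical formulation. The fit passes when every
statistic is below 1.10; well-behaved fits at the default protocol
reach about 1.004 or better. Geweke z-scores (windows: first 10%
versus last 50%, spectral-density-at-zero variances from an AR fit)
and effective sample sizes (autocorrelation sum with Geyer's
pairwise-positive truncation, pooled across chains) are attached for
reference. `render_report()` withholds estimates whenever the gate
failed unless explicitly overridden.

`prior_informativeness_check()` implements the weak-prior rule adopted
by the protocol: every coefficient's posterior SD should be below 10%
of its prior SD. See the caveat below — on the default synthetic
sample this rule genuinely fails for near-empty covariate cells, and
the package reports that honestly rather than substituting a smaller
SD proxy.

**Odds ratios.** `odds_ratio_table()` reports, per slope, the point
estimate $\exp(\mathbb{E}[\beta_k])$ (the exponentiated posterior
mean; $\mathbb{E}[e^{\beta_k}]$ is available via `point =
"mean_exp"`), the SD of the exponentiated draws (the only reading that
yields an SD on the odds scale), equal-tailed 95% bounds as the
exponentials of the 0.025/0.975 coefficient-scale quantiles (equal to
quantiles of the exponentiated draws by monotonicity), the percentage
effect $(\mathrm{OR}-1)\times 100$, and a significance flag set when
the interval excludes 1. Quantiles interpolate linearly between order
statistics (R's default type 7), which the tests pin down.

## The synthetic survey generator

The original analysis used 640 smokers extracted from a national
school-based youth tobacco survey; the micro-data are not
redistributable, so the package ships a generator that emulates the
published structure of that sample and makes every stage testable:

* grade shares 0.398 / 0.325 / 0.277 (multinomial);
* some forty covariates at their published marginal means: independent
  Bernoulli for binary items; binomial on codes $0..6$ scaled to the
  target mean for count-like items (a two-parameter, bounded,
  reproducible choice — only means and SDs of these items are
  published, and the binomial matches the means exactly while keeping
  integer codes); mutually exclusive sets (age groups, parental
  smoking, usual brand) drawn as single categoricals and one-hot
  encoded with the reference levels dropped, any unassigned
  probability mass going to the reference level;
* grade intercept deviations $N(0, \sigma_\mu^2)$ with
  $\sigma_\mu = 0.3$ by default — a stipulation, since the source
  analysis never reports its group-scale posterior; 0.3 keeps
  grade-to-grade prevalence differences in the plausible
  few-percentage-point range;
* slopes defaulting to the logs of the published odds ratios, so
  recovery studies run at realistic effect sizes (the three age groups
  are treated as an abstract exhaustive categorical — published
  descriptions of the middle group's upper age boundary are
  inconsistent, and nothing downstream depends on the labels);
* an intercept either fixed or auto-calibrated by bisection on a fixed
  $10^5$-row Monte Carlo draw so the simulated prevalence of the
  outcome matches the published 63.3%.

When `generate_dataset()` calibrates the intercept it conditions on
the dataset's realized grade deviations: with three groups, the
realized mean grade effect shifts a dataset's prevalence by a few
percentage points (SD $\approx$ 0.04 on the probability scale at
$\sigma_\mu = 0.3$), so calibrating only against the covariate
distribution could not keep the simulated prevalence within a fraction
of a percentage point of the target. A standalone
`calibrate_intercept()` call without realized deviations integrates
the grade effect out instead, which centers the prevalence correctly
*across* datasets rather than within one.

**What the generator does not emulate.** Covariates are drawn
independently (the source publishes only marginals; a correlated
pattern in the real survey would change posterior SDs and could slow
mixing), item non-response is not simulated (the analysis protocol
drops incomplete rows), and the survey's two-stage cluster design and
weights are ignored, as they are in the model itself. Passing tests
therefore demonstrate that the machinery is correct under the stated
generating process, not that the published coefficient values are
reproduced — they cannot be, without the original micro-data.

## Known limitation: the 10% prior rule on sparse cells

The rarest covariate in the published table, the Safari brand dummy,
has marginal mean 0.006: a 640-row sample contains about four such
respondents. Four Bernoulli observations contribute likelihood
information of order $4 \times \pi(1-\pi) \approx 0.9$, so that
slope's posterior SD is at best about 1 — right at 10% of its prior SD
of 10 — and when the few cases happen to share one outcome value the
likelihood cannot bound the coefficient on one side at all and the
posterior SD grows toward the prior's scale. The global intercept
ratio also hovers near 10%, because with three groups the split
between $\alpha_0$ and the group effects is weakly identified and
$\sigma_\mu$'s heavy-tailed prior widens $\alpha_0$'s marginal. The
prior-informativeness gate is therefore expected to fail on faithful
posterior SDs at this sample size, and the package reports the
computed ratios as they are. (The published report's SD column is far
too small to be a posterior SD at $N = 640$ — it is plausibly a Monte
Carlo standard error — and we deliberately do not emulate it.)

## Recovery studies and problem sizes

`run_recovery_study()` validates the whole pipeline by simulation:
$R$ replicates of generate → fit → summarize at seeds derived from a
base seed, scoring per-parameter bias, RMSE and empirical coverage of
the equal-tailed intervals, aggregating only replicates that pass the
convergence gate and flagging the study as unreliable above 20% gate
failures. The default study uses a three-covariate model at
$N = 400$ with shortened chains ($2 \times 1500$, warmup 750):
coverage assessment needs replicates more than it needs long chains,
and at eight unconstrained dimensions 750 kept draws per chain
estimate a 95% interval adequately. The single-fit protocol
($2 \times 4000$, warmup 2500) remains the default everywhere else.

The oracle check for the sampler uses a two-parameter non-hierarchical
logit on 60 rows, where dense trapezoid quadrature on a
$400 \times 400$ grid over $[-10, 10]^2$ is effectively exact; NUTS
posterior means are required to agree within three Monte Carlo
standard errors and posterior SDs within 10%.

## Numerical choices, in brief

* `inverse_logit` and the likelihood never overflow for |logit| up to
  several hundred; gradients propagate `y - pi` directly.
* Divergence threshold 1000 on the energy error; initial step size by
  the classical doubling/halving heuristic; dual-averaging constants
  $\gamma = 0.05$, $t_0 = 10$, $\kappa = 0.75$.
* Step size collapse below $10^{-10}$ during adaptation raises a hard
  error naming a parameter-scale problem rather than looping forever.
* Zero-variance (constant) chains make Gelman–Rubin and ESS signal an
  undefined statistic instead of returning a number.
* Equal-tailed intervals use type-7 quantiles; ESS is capped at 1.5×
  the draw count to avoid advertising super-efficiency.
* The bisection for the generator intercept runs on mean probabilities
  (not sampled outcomes), so it is smooth and deterministic; targets
  unreachable within $\alpha_0 \in [-30, 30]$ fail loudly.
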