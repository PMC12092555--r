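---
title: "Robust model-averaged Bayesian t tests: models, priors, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust model-averaged Bayesian t tests: models, priors, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbttest)
```

## The model ensemble

A two-sample comparison is usually preceded by assumption checks — equal
variances? outliers? — whose all-or-none outcomes then pick a single test.
`mbttest` instead treats the assumptions themselves as model components and
averages over them. Every observation in group $g \in \{1, 2\}$ is modelled
as

$$y_{gi} \sim \begin{cases}
\mathrm{Normal}(\mu_g, \sigma_g) & \text{normal-likelihood models},\\
\mu_g + \sigma_g\sqrt{\tfrac{\nu-2}{\nu}}\, t_\nu & \text{t-likelihood models},
\end{cases}$$

where the $t$ scale is shrunk by $\sqrt{(\nu-2)/\nu}$ so that $\sigma_g$ is
the *standard deviation* of the observable under both likelihoods — without
this, Cohen's $\delta$ would silently change meaning across the ensemble.

The group parameters are driven by a common parametrization:
$\mu_{1,2} = \mu \mp \tfrac{1}{2}\delta\sigma$ and
$\sigma_1^2 = 2\sigma^2(1-\rho)$, $\sigma_2^2 = 2\sigma^2\rho$, so that
$\sigma_1^2 + \sigma_2^2 = 2\sigma^2$ (the grand scale is the
variance-average of the group scales) and $\rho$ is group 1's share of the
total precision. The ensemble crosses three binary choices — effect
($\delta = 0$ vs. free), variances ($\rho = 0.5$ vs. free), likelihood
(normal, $\nu = \infty$, vs. $t$ with free $\nu$) — into 8 models
(`romb8`); the normal-likelihood half is the 4-model ensemble (`mb4`), and
the equal- or unequal-variance pairs are the classical Bayesian Student and
Welch tests.

## Priors and their calibration

* $\delta \sim \mathrm{Cauchy}(0, 1/\sqrt 2)$ (location, scale; unitless).
  An optional truncation supports directional tests, and the scale is free —
  e.g. `prior_settings(delta_scale = 0.05)` encodes a strong expectation of
  tiny effects.
* $\rho \sim \mathrm{Beta}(1.5, 1.5)$. Through
  $SDR = \sigma_1/\sigma_2 = \sqrt{(1-\rho)/\rho}$ this places about 90% of
  its mass on SD ratios between 1/3 and 3
  (`prior_mass_sdr_interval(1/3, 3)` = `r round(prior_mass_sdr_interval(1/3, 3), 4)`),
  i.e. on "realistic" degrees of variance heterogeneity.
* $\nu \sim 2 + \mathrm{Exponential}(1)$ (unitless degrees of freedom). The
  shift by 2 guarantees a finite mean and variance of the $t$ likelihood —
  a requirement of the $\delta$ parametrization — and concentrates mass on
  small $\nu$ (prior mean 3, IQR 2.3–3.4), keeping the $t$ half of the
  ensemble genuinely distinct from the normal half so that the outlier
  Bayes factor is diagnostic.
* $p(\mu, \sigma) \propto 1/\sigma$ (Jeffreys), shared by all models. The
  improper constant cancels from every Bayes factor, and the construction
  makes all Bayes factors exactly invariant under affine rescaling of the
  data; with $\rho$ fixed at 0.5 and a normal likelihood it reproduces the
  standard default-prior equal-variance Bayes factor.
* Prior model probabilities are uniform (1/8 or 1/4) by default,
  overridable via `prior_settings(model_probs = ...)`.

On the ρ/SDR direction: with $\rho$ defined as group 1's *precision* share,
a large $\rho$ means a *small* group-1 variance, hence
$SDR = \sqrt{(1-\rho)/\rho}$ (the worked variance pair 2 and 4 gives
$\rho = 2/3$ and $\sigma_1/\sigma_2 = \sqrt{1/2}$). Conventions differ
between software packages; `sdr_from_rho(..., convention = "group2/group1")`
and the `sdr_convention` field of `prior_settings()` flip the reported
ratio. The symmetric default Beta prior makes the 90%-interval statement
invariant to this choice.

## Computing marginal likelihoods

**Normal-likelihood models** depend on the data only through per-group
$(n, \bar y, s)$. Conditional on $(\delta, \rho)$, integrating $\mu$ and
then $u = 1/\sigma$ under the Jeffreys prior reduces the marginal to
$\int_0^\infty u^{N-2}\exp(-\tfrac{p}{2}u^2 + qu)\,du$, a noncentral-$t$
density in disguise. We evaluate this 1-D integral by mode-centred
Gauss–Legendre quadrature in log space (120 nodes over ±12 posterior SDs)
rather than through R's noncentral-$t$ density, which loses precision at
large noncentrality; the test suite compares the two routes in the bulk.
The remaining integral over the free members of $(\delta, \rho)$ uses
tensor Gauss–Legendre rules after variable transforms chosen for
*analyticity*, not just boundedness:

* $\delta$ via its Cauchy prior quantile ($\tan$ map) — analytic, and the
  prior becomes the uniform measure;
* $\rho$ via $\rho = \sin^2\theta$, which absorbs the square-root endpoint
  behaviour of the Beta(1.5, 1.5) density into an analytic integrand (exact
  for half-integer shapes).

Node counts double (65 → 1025) until successive estimates agree to a 1e-8
relative tolerance; non-convergence is an error carrying the achieved
tolerance, never a silent result.

**t-likelihood models** have no sufficient statistics, so the free members
of $(\mu, \log\sigma, \delta, \mathrm{logit}\,\rho, \log(\nu-2))$ are
sampled by an adaptive random-walk Metropolis sampler (Rcpp): 4 chains,
1000 warmup iterations with Robbins–Monro scale and running-covariance
adaptation (target acceptance 0.3), then 2000 kept draws per chain at
thinning 3 with the kernel frozen. Convergence is gated on split-chain
$\hat R \le 1.01$ and effective sample sizes (spectral estimator); a
failing fit is retried with 4× the iterations and then errors. The log
marginal likelihood comes from the iterative optimal-bridge identity
between the posterior draws and a multivariate-normal proposal
moment-matched to half of them (tolerance 1e-6, cap 1000 iterations), with
a relative-MSE standard error that accounts for autocorrelation via an AR
spectral estimate. All stochastic steps derive per-chain seeds from the
user seed, so every fit is exactly reproducible.

**The oracle.** `logml_grid_oracle()` is a deliberately unclever
tensor-product Gauss–Legendre integration of likelihood × prior over all
free parameters (up to 5 dimensions, ≤ ~1e8 nodes), with analytic $\tan$
compactifications for $\mu$ and $\log\sigma$. It shares no code path with
either production estimator and anchors the test suite: quadrature fits
must match it to 1e-6, sampler fits to 3 Monte-Carlo SEs.

## Model combination and averaging

Posterior model probabilities are the softmax of
$\log p(y \mid M) + \log p(M)$ (log-sum-exp, stable to $|\log ML| \sim 10^3$).
Inclusion Bayes factors divide posterior by prior odds of a model *set*
(effect, unequal variances, $t$ likelihood); they are computed directly
from log marginal likelihoods so that one-sided dominance does not produce
0/0. Model-averaged posteriors are mixture draws: sample a model by its
posterior probability, then a parameter value from that model — with
spec-implied constants ($\delta = 0$, $\rho = 0.5$, $\nu = \infty$)
entering as point masses. $\nu$ draws from normal models enter as
$+\infty$; quantiles are taken on the extended real line (type-1), so the
reported median is $\infty$ exactly when normal-likelihood models carry
more than half of the mixture. Because figures and text in this literature
alternate between conditional and model-averaged summaries, both are
always computed and labelled. Credible intervals are central (equal-tailed)
from 1e5 mixture draws by default.

Quadrature fits carry no $(\mu, \sigma)$ draws; their $(\delta, \rho)$
posterior draws are generated on demand by inverse-CDF sampling on a fine
prior-quantile grid with within-cell jitter (4096 cells in 1-D, 256² in
2-D), which is ample for mixture summaries reported to two decimals.

## Sequential analysis, replication, and the simulation harness

Sequential trajectories re-fit the ensemble on nested data subsets (default
"pairwise": one new observation per group per checkpoint); Bayes factors
are full-data recomputations at each checkpoint, so there is no path
dependence and exchangeability within a checkpoint is exact. Replication
Bayes factors use the quotient identity
$BF_{rep} = BF_{combined}/BF_{original}$, which equals updating the priors
(including the model probabilities) to the original study's posterior
while avoiding density estimation of posteriors.

The simulator draws data under a factorial design — $\delta \in \{0, 0.3,
0.5\}$, $SDR \in \{1, 1.5, 2\}$, $\nu \in \{\infty, 10, 5\}$, total $n \in
\{20, 50, 100\}$, allocation $n_1{:}n_2 \in \{1/2, 1, 2\}$ — with group
sizes $n_2 = \mathrm{round}(N/(1+r))$, $n_1 = N - n_2$ (total 50 at
allocation 2 gives 33/17). $t$-generated data are scaled by
$\sigma_g\sqrt{(\nu-2)/\nu}$ so the population SD equals its target and
$\delta$ stays comparable across $\nu$; whether heavier tails should
instead inflate the realized SD (raw $t$ scale, changing the effective
$\delta$ by $\sqrt{\nu/(\nu-2)}$) is a genuine design fork, so
`raw_t_scale = TRUE` exposes the alternative. Evidence distortion factors
(candidate BF / matching-test BF) are ratios, so study summaries use
geometric means and log-scale quantiles. The reference test per condition
is Student for normal equal-SD data, Welch for normal unequal-SD data, and
the matching $t$-likelihood model pair otherwise. Per-replicate seeds are
derived from the study seed, making results independent of evaluation
order and worker count.

## What the generator does and does not emulate

The synthetic conditions cover mean shifts, variance heterogeneity and
symmetric heavy tails — the three axes the ensemble is built to detect.
They do not emulate skewness, discreteness (e.g. Likert scales), serial
dependence, or contamination that differs between groups; passing tests
therefore demonstrate calibration and evidence-direction properties under
the stated families, not robustness to every real-data pathology.

## Problem sizes and numerical choices

The bundled checks run at desk scale, chosen to keep the full suite in the
minutes range while leaving Monte-Carlo error well below the decision
thresholds: oracle comparisons use a 4+4-observation data set (where the
oracle grid is densest per dimension), parameter recovery uses 200
simulated data sets at $n = 50$ per group with a lightened but
convergence-gated sampler (500 warmup, 1000 kept per chain), and the
evidence-distortion properties use 100 replicates per condition. The full
3⁵-condition, 1000-replicate factorial is supported through
`full_condition_grid()` and produces the same record schema.
Parameter-recovery checks evaluate the estimate averaged across the models
in which the parameter is present — the convention this literature uses in
its estimation figures; the all-model mixture (which retains a point mass
at zero under null models and is therefore deliberately shrunk) is always
computed and labelled alongside it.

Degenerate inputs fail loudly: groups need at least two finite
observations and nonzero variance; `rho` and `sdr` transforms reject
boundary values; `bayes_factor()` refuses fits whose data hashes differ;
and reports are only emitted with passing diagnostics. Ties in the
evidence labels are broken upward (a Bayes factor of exactly 3 counts as
"moderate"), and a Bayes factor of exactly 1 is labelled equivocal.

## Known limitations

* Paired or one-sample designs, more than two groups, and asymmetric
  likelihood families are out of scope.
* The exact nuisance priors behind published implementations vary; the
  Jeffreys choice here is validated against this package's own oracle, and
  equal-variance results coincide with the standard default-prior test.
  Published numbers computed under a different nuisance construction may
  differ slightly for unequal-variance models.
* The random-walk sampler is adequate for the ≤ 5-dimensional posteriors
  here but would need replacing (e.g. gradient-based kernels) for
  substantially larger models.
* Reconstructing raw data from summary statistics
  (`fixture_from_summary()`) pins only the first two moments; t-likelihood
  results on such fixtures depend on the unconstrained higher moments and
  should be read as illustrative, not as a reanalysis of the original raw
  data.
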