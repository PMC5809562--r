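---
title: "Hierarchical multinomial processing tree models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multinomial processing tree models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmpt)
```

## The measurement model

Multinomial processing tree (MPT) models explain categorical responses as
the outcome of a finite sequence of latent cognitive events.  Each branch
of a tree reaches exactly one observable category, and its probability is a
product of transition probabilities: for branch $i$ ending in category $k$,

$$P(B_{ik} \mid \theta) \;=\; c_{ik} \prod_{s=1}^{S}
  \theta_s^{a_{iks}} (1-\theta_s)^{b_{iks}},$$

where $a_{iks}$ and $b_{iks}$ count how often parameter $\theta_s$ and its
complement occur on the branch and $c_{ik}$ collects numeric constants.
Category probabilities are sums of branch probabilities, and within each
tree they form a simplex.  The data are product-multinomial: independent
multinomial counts per tree, per participant.

`parse_eqn()` reads this structure from the EQN interchange format (first
line always a comment; each line `tree category equation`).  Restrictions
— equality chains like `D1 = D2 = D3` and constants like `g = 0.5` — are
applied symbolically: equality classes rename parameters to the class
representative and accumulate exponents, constants fold into $c_{ik}$, so
the restricted model evaluates *exactly* like the original at mapped
parameter values.  `validate_model()` checks the simplex identity
numerically and reports the rank of the Jacobian of category probabilities
as a local-identifiability diagnostic: the bundled source-monitoring model
(`eqn_2htsm()`) has 8 parameters but only 6 free categories, so its rank is
below 8 until the standard restrictions collapse it to 4 parameters.

## Two population models

Both hierarchical variants keep the MPT likelihood per participant and
differ in the population distribution of the individual parameter vectors
$\theta_p$.

**Latent-trait model.**  The probit transforms follow a multivariate
normal, $\Phi^{-1}(\theta_p) = \mu + X\beta + \delta_p$ with $\delta_p \sim
\mathrm{MVN}(0, \Sigma)$.  Correlations between parameters are modelled
explicitly.  The prior on $\Sigma$ is a *scaled* inverse Wishart,
$\Sigma = \mathrm{diag}(\xi)\, Q\, \mathrm{diag}(\xi)$ with $Q \sim
\mathrm{InvWishart}(I_S,\, S+1)$ and $\xi_s \sim \mathrm{U}(0, 10)$: the
redundant scaling decouples the marginal SDs from the correlation backbone
and removes most of the prior's influence on the variances.  Group means
get standard-normal priors, which imply *uniform* priors for the
probability-scale means $\Phi(\mu_s)$.  Priors here are parameterized by
mean and standard deviation; a BUGS-style precision notation such as
`dnorm(0, 4)` corresponds to `mu_sd = 0.5`.

**Beta-MPT.**  Each parameter follows an independent
$\mathrm{Beta}(\alpha_s, \beta_s)$ population distribution with
$\mathrm{Gamma}(1, 0.1)$ hyperpriors on both shapes.  Group mean and SD are
derived from the shapes at every draw; the derived SD can never exceed
$\sqrt{\bar\theta(1-\bar\theta)}$.  An approximately uniform prior on
(mean, SD) via a zeros-style trick is deliberately *not* offered: it is
numerically fragile in the engines that popularized it, and the gamma
default encodes the reasonable expectation that individuals differ, but
moderately.

## The sampler

Sampling is by a dependency-free Metropolis-within-Gibbs sweep written for
posteriors of this scale (tens of participants, a handful of parameters).
For the latent-trait model one sweep updates, in order:

1. the probit values $z_{ps}$, columnwise over participants with adaptive
   scalar random walks (the multinomial likelihood is evaluated vectorized
   over participants);
2. $(\mu_s, \beta_s)$ by conjugate Bayesian regression, conditioning on the
   remaining columns through the conditional normal of $\delta_s \mid
   \delta_{-s}$;
3. $Q$ by its conjugate Wishart full conditional given
   $\varepsilon = \mathrm{diag}(\xi)^{-1}\delta$;
4. each $\xi_s$ twice: once *non-centered* — holding
   $\varepsilon$ fixed and rescaling the whole column against the
   likelihood — and once *centered* against the prior of $\delta$.
   The interweaved pair is what carries the chain across the
   small-$\sigma$ funnel; without it the $\sigma_s$ chains mix an order of
   magnitude slower when the true SD is small;
5. the slope variances $g_s$ by inverse-gamma Gibbs
   ($g_s \sim \mathrm{InvGamma}(1/2, v^2/2)$, $v = 1$, the inverse
   $\chi^2(1)$ default; a fixed $g_s = 1$ is available via `fixed_g`).

Proposal scales adapt by log-scale Robbins–Monro (step $1/\lceil i/50
\rceil$, target acceptance 0.35) during burn-in only and are frozen
afterwards, so the retained chain is a time-homogeneous Markov chain.
Chains start from a pooled least-squares projection of the smoothed
observed proportions onto the model manifold, plus chain-specific jitter.
Per-chain seeds derive deterministically from the master seed, so a run is
fully reproducible from `(seed, settings, data)`.

The beta-MPT kernel updates individual parameters on the logit scale
(beta-prior target with the Jacobian) and the shapes on the log scale.

Defaults mirror common practice for these models: 20,000 iterations, 2,000
burn-in, thinning 5, three chains.  Convergence is summarized by
split-chain $\widehat R$ and an effective sample size from chain-averaged
autocorrelations truncated at the first negative pair.  A fit with any
group-level $\widehat R \ge 1.05$ is returned *with a loud warning*, never
silently; `extend_run()` continues all chains from their stored final
states.

## Predictors

Continuous covariates enter the probit regression z-standardized (mean 0,
variance 1, divisor $P$), so the default slope priors
$\beta_{sk} \sim N(0, g_s)$ with the inverse-$\chi^2(1)$ prior on $g_s$
form a scale-invariant multivariate Cauchy per parameter.  Unstandardized
slopes (standardized slope divided by the covariate's population SD) are
reported alongside.  Discrete factors are either fixed effects
(sum-to-zero coding, $L-1$ columns) or random effects (indicator coding,
$L$ columns sharing one variance $g$ with the same inverse-$\chi^2(1)$
prior).  `group_means_by_factor()` reconstructs per-level probability-scale
means $\Phi(\mu_s + \eta_{sl})$, recovering the left-out fixed-factor level
from the sum-to-zero constraint.

## Fit assessment

Posterior-predictive checks use two discrepancies: $T_1$, a Pearson
distance between observed and expected *mean* frequencies, and $T_2$, the
sum of absolute differences between observed and expected covariances of
the individual frequencies, standardized by expected SDs (off-diagonal
pairs only — the statistic is about *co*variation; the diagonal is already
covered by $T_1$).  Expected moments per draw are computed analytically
from that draw's $\theta$ matrix (multinomial mean and covariance within
participant, plus between-participant dispersion of the expected
frequencies), not by nested simulation, which removes one layer of Monte
Carlo noise.  The PPP value is the fraction of draws with
$T_{\mathrm{obs}} < T_{\mathrm{pred}}$; under a well-specified model it
concentrates in the middle of $(0,1)$ but is *not* uniform, so the package
treats it as a heuristic flag, not a calibrated test.  DIC uses the
deviance conditional on the individual-level parameters — the focus an
external Gibbs engine reports — with $p_D = \bar D - D(\bar\theta)$.

## Homogeneity tests

Before pooling or partial pooling, `chisq_participant_heterogeneity()`
tests whether all participants share one category distribution: per tree,
pooled proportions give expected counts $n_{pt}\hat p_k$ and the summed
Pearson statistic has $(P-1)\sum_t (K_t - 1)$ degrees of freedom.  This
form is fixed by that df identity (a 24-participant design with three
3-category trees gives df 138).  The permutation variant re-randomizes
responses *within each item* across participants, which preserves item
margins and therefore stays valid when items are heterogeneous; its p
value uses the add-one estimator to avoid exact zeros.  Item homogeneity
can be tested by transposing the roles of participants and items in the
long-format input.

## Covariate correlations

Beyond regression, `covariate_correlations()` computes the Pearson
correlation between a covariate and the individual parameters at every
retained draw, and `population_correlation()` corrects these for sampling
error: for each draw of the sample correlation $r$, the posterior density
of the population correlation $\rho$ (uniform prior, exact small-sample
density of $r$ given $\rho$ with its hypergeometric factor, evaluated on a
2001-point grid) is computed, and the densities are averaged.  The
averaged posterior is wider than the spread of the $r$ draws alone, as it
must be; the grid construction reproduces the behaviour of the analytic
procedure it approximates (correct limits, symmetry at $r = 0$,
monotonicity in $n$) without its special-function machinery.

## Synthetic data and the recovery benchmark

`gen_mpt()` draws one multinomial per participant and tree from any fixed
$\theta$ matrix; `gen_trait_mpt()` and `gen_beta_mpt()` add the two
population models on top.  The reference benchmark `sim_design_2htsm()`
fixes the study conditions used throughout the tests and the acceptance
script: 50 participants; 16 items per source tree and 32 new items; probit
means $a = 0.3$, $b = -0.1$, $d = 0.6$ and $D = \Phi^{-1}(0.62) \approx
0.31$ with probit SDs $0.6, 0.5, 1.0, 0.2$; and a standard-normal
covariate with standardized slopes $\beta^D = -0.3$ and $\beta^d = 0.5$.
The recognition-memory mean is stated on the probability scale (0.62)
because that is the scale on which the benchmark's recovery targets are
defined.

`recovery_simulation()` repeats generate–fit–summarize, gates each
replication on group-level $\widehat R < 1.05$ (re-fitting with doubled
iterations, then excluding), and aggregates posterior means, averaged 95%
CI bounds, absolute bias, CI coverage, and — for slopes — the percentage
of replications whose CI excludes zero.  Expected behaviour at this
design: group means recover with small bias; $\sigma_d$ is *overestimated*
(the source-memory parameter is observed only conditionally on
recognition, so the data carry little information about its spread);
$\beta^D$ is estimated precisely and its CI excludes zero in essentially
every replication, while $\beta^d$ is noisier.

### Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the benchmark at 10 and 15
replications respectively, with 5,000 iterations (2,000 burn-in, thinning
3, 3 chains) per fit, and compare recovery averages within Monte-Carlo
standard errors computed from the replications themselves.  These sizes
were chosen as the smallest at which the between-replication SEs are tight
enough for the comparisons to be informative; the generating conditions
themselves are never scaled.  The calibration loop for posterior-predictive
p values uses 50 short fits of a small two-tree model in which both
parameters are directly identified.

## What the synthetic benchmark does not emulate

The generators produce participants that follow the assumed population
model exactly, with items exchangeable within trees.  Real data bring item
heterogeneity (only the permutation test addresses it here; there are no
crossed participant-by-item random effects), response omissions,
and populations that follow neither a probit normal nor independent betas.
Passing recovery and calibration tests therefore demonstrates the
correctness of the implementation under its own assumptions, not the
adequacy of those assumptions for any particular data set.

## Numerical choices and degenerate inputs

* $\theta$ values are clipped $10^{-9}$ from the boundary before logs, so
  proposals at the edge of the cube never produce $-\infty$.
* Empty data (all counts zero) are legal and return the priors — used as a
  prior-recovery oracle in the tests.
* Categories with zero pooled counts are dropped from the heterogeneity
  test with a warning and a df correction.
* Sample correlations of exactly $\pm 1$ are shrunk by $10^{-6}$ before
  the population-correlation grid.
* Equality-class representatives are the first-listed names, matching how
  restriction files read.
* The EQN dialect skips the first line unconditionally, skips `#` lines,
  and treats `*` as optional around parentheses, for compatibility with
  files written for other MPT tools.

## Known limitations

* No item random effects; participant heterogeneity only.
* DIC is reported with the conditional-likelihood focus; no WAIC/LOO, no
  Bayes factors.
* The Metropolis-within-Gibbs sampler is adequate for the scale it was
  built for; models with dozens of parameters or strong posterior
  correlations will need longer runs (`extend_run()`) and may warrant a
  gradient-based engine instead.
* Between-subjects comparisons of separately fitted models pair draws by
  index; the two posteriors are independent, so this is only a convenience
  for forming difference draws.
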