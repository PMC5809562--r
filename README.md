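# hmpt — hierarchical Bayesian multinomial processing tree models

Multinomial processing tree (MPT) models explain categorical responses —
"Source A", "Source B", "New" in a source-monitoring task, hit/miss in a
detection task — as the outcome of a small number of latent cognitive
processes arranged in probability trees.  Fitting one MPT model to data
aggregated over participants assumes everyone shares the same parameters;
when participants differ, that assumption biases estimates and breaks the
goodness-of-fit tests.  `hmpt` is for researchers in cognitive
psychometrics who need the hierarchical alternative: every participant gets
their own parameter vector `θ_p`, tied together by a population
distribution, estimated by MCMC.

Two population models are implemented:

* **latent-trait MPT** — probit-transformed parameters follow a
  multivariate normal, `Φ⁻¹(θ_p) = μ + Xβ + δ_p`,
  `δ_p ~ MVN(0, Σ)`, with a scaled inverse-Wishart prior
  `Σ = diag(ξ) Q diag(ξ)`; supports continuous covariates and discrete
  fixed/random factors as predictors on the probit scale;
* **beta-MPT** — each parameter follows an independent
  `Beta(α_s, β_s)` population distribution with `Gamma(1, 0.1)`
  hyperpriors.

Around the samplers the package provides: an EQN-format model parser with
symbolic equality/constant restrictions and within-subjects replication;
participant-homogeneity tests (asymptotic χ² and an item-wise permutation
test); posterior-predictive fit statistics `T1`/`T2` with PPP values and
DIC; within- and between-subjects comparisons; sampling-error-corrected
population correlations; and synthetic-data generators with a
parameter-recovery harness.  See `vignettes/hierarchical-mpt.Rmd` for the
statistical details and design decisions.

## Worked example

The bundled two-high-threshold source-monitoring model (2HTSM) has three
trees (expected source `E`, unexpected source `U`, new items `N`), nine
response categories, and eight parameters — too many for its six free
categories, so the standard restrictions `D1 = D2 = D3`, `d1 = d2`,
`a = g` reduce it to four: item recognition `D1`, source memory `d1`,
source guessing `a`, and the old/new guessing bias `b`.

```r
library(hmpt)

model <- apply_restrictions(parse_eqn(eqn_2htsm()), restrictions_2htsm())
model
#> MPT model: 3 tree(s), 9 categories, 16 branches, 4 parameter(s)
#> Parameters: a, b, d1, D1

# synthetic data at the package's reference design: 24 participants,
# 16 + 16 + 32 items, with a covariate that shifts D1 and d1
des <- sim_design_2htsm()
sim <- gen_trait_mpt(24, des$items_per_tree, des$spec, des$model, seed = 42)

# are participants heterogeneous at all?
chisq_participant_heterogeneity(sim$data)
#> Chi-square test of participant heterogeneity
#>   X2(138) = 391.1, p = 4.6e-26

fit <- fit_trait(model, sim$data, covariates = sim$covariates,
                 predictors = predictor_spec("D1 d1 ; pred"),
                 settings = mcmc_settings(6000, 2000, 4, 3, seed = 1))
fit
#> Hierarchical MPT fit (trait), 24 participants, 4 parameters
#>     parameter    mean     sd    q2.5  q97.5  rhat  ess
#>        mean_a  0.6462 0.0667  0.5144  0.776 1.001 1865
#>        mean_b  0.4871 0.0563  0.3747  0.598 1.001 1557
#>       mean_d1  0.8326 0.1124  0.5637  0.986 1.002  706
#>       mean_D1  0.6094 0.0276  0.5567  0.662 1.004  855
#>       sigma_a  0.7652 0.1711  0.4886  1.162 1.006 1105
#>  ...
#>  beta_D1:pred -0.2568 0.0694 -0.3953 -0.124 1.003 1020
#>  beta_d1:pred  0.9816 0.6828 -0.1159  2.575 1.005  396
```

The χ² test rejects homogeneity decisively (the data were generated with
real individual differences), so the hierarchical fit is warranted.
`mean_*` rows are probability-scale group means `Φ(μ_s)`: recognition
`D1` recovers near its generating value 0.62, guessing `b` near 0.46.
`sigma_*` rows are probit-scale SDs.  The covariate's standardized slope on
`D1` is clearly negative (95% CI [−0.40, −0.12], generating value −0.3),
while the slope on `d1` is positive but noisy — source memory is observed
only conditionally on recognition, so the data carry less information about
it.  `rhat`/`ess` columns confirm convergence (all R̂ < 1.05); a
non-converged fit warns loudly and can be continued with `extend_run()`.

Fit is checked against posterior-predictive mean frequencies and
covariances:

```r
ppp(fit, M = 300, seed = 1)
#> Posterior-predictive checks (M = 300)
#>   T1 (means):       observed 0.22 | predicted 0.23 | PPP = 0.540
#>   T2 (covariances): observed 4.54 | predicted 4.86 | PPP = 0.610
dic(fit, M = 300)
#> DIC = 2216.2 (pD = 59.2)
```

PPP values near the middle of (0, 1) indicate no detectable misfit, as
expected for well-specified data.  Small values (< .05) flag misfit.

The same workflow runs without writing R, from text files alone:

```sh
Rscript inst/cli/hmpt.R run --config analysis.cfg        # key = value file
Rscript inst/cli/hmpt.R fit-trait --eqn model.eqn --data freq.csv \
    --restrictions restr.txt --iter 20000 --seed 1 --out-summary out.txt
```

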