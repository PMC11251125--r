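---
title: "Methods: the bivariate STARTS model in bstarts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bivariate STARTS model in bstarts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the priors and sampler, the
fit-evaluation machinery, and the design decisions behind **bstarts**. It is
the package's methodological reference; the README shows the workflow.

## The model

Two constructs are measured repeatedly on each dyad: a child
emotional-difficulties composite (EM, the five-item SDQ emotional-symptoms
scale, 0–10) and a parent-child closeness composite (CL, the seven-item
Pianta closeness scale, 7–35), at four waves (child ages 3, 5, 7, 9). The
STARTS (Stable Trait, Autoregressive Trait, State) decomposition writes each
observed score as

$$Y_{x,t} = CST_x + ART_{x,t} + S_{x,t}, \qquad x \in \{EM, CL\},\; t = 1,\dots,4,$$

with three latent sources of variance:

* **Completely stable trait** $CST_x$: time-invariant between-dyad
  differences. The two traits are correlated
  ($\mathrm{Cov} = $ `cst_cov`).
* **Autoregressive trait** $ART_{x,t}$: the slowly changing component,
  following a first-order vector autoregression across waves,
  $$ART_{t+1} = B_t\,ART_t + D_{t+1}, \qquad D_{t+1} \sim N(0, Q).$$
  The diagonal of $B_t$ holds the *carryover* coefficients (equated over
  intervals, one per construct); the off-diagonal holds the *cross-lagged*
  (spillover) coefficients, freely estimated per interval. The wave-1 trait
  pair has free covariance `art1_cov`; the disturbance covariance $Q$ is
  equated across intervals (see Design decisions).
* **State** $S_{x,t}$: the occasion-specific remainder. There is no separate
  measurement-error term — the state absorbs it. State variances are free
  per wave and construct; the within-wave state covariance is equated
  across waves.

With four waves this gives 26 free parameters against 36 nonredundant
observed moments, so the model is overidentified. (A two-wave version is
not: 18 parameters against 10 moments. This is why reduced-scale
calibration experiments in the test suite shrink the *sample size* and fix
the state block rather than dropping waves.)

All matrices use the fixed construct order (EM, CL) and the column order
`EM1..EM4, CL1..CL4`.

### Implied moments and likelihood

Because the model is linear-Gaussian, the latent components integrate out
exactly. With $A_t = \mathrm{Cov}(ART_t)$,
$A_{t+1} = B_t A_t B_t' + Q$ and
$\mathrm{Cov}(ART_s, ART_t) = (B_{s-1}\cdots B_t)\,A_t$ for $s > t$, the
implied covariance of the eight observed variables is assembled per wave
pair as `cst_cov + Cov(ART_s, ART_t) + 1{s = t} * state block`
(`starts_implied_moments()`).

The likelihood (`starts_loglik()`) is the multivariate-normal density of
each dyad's *observed* coordinates under these implied moments
(full-information treatment of missingness). Rows are grouped by
missingness pattern, and each pattern is evaluated from its sufficient
statistics, so the cost per evaluation is independent of the number of
dyads — a complete-data panel collapses to a single
$(n, \bar y, S)$ triple. This is what makes desk-scale estimation at
$n = 7{,}507$ cheap.

### Scaling convention

Because the two composites live on different ranges, each construct's four
wave columns are divided by the *average of its four wave SDs* and then
mean-centred (`scale_by_average_sd()`). This leaves the average
within-construct variance near 1 while preserving wave-to-wave variance
ratios. Note a small Jensen gap: with the published wave SDs the mean of the
four scaled variances is 1.022 for EM, not exactly 1 — the average *SD* is
1 by construction, not the average variance. Centring is applied because
the model carries no mean structure by default; an intercept-per-variable
option (`means_free = TRUE`) exists for uncentred metrics. The scaling
constants are stored on the panel for exact back-transformation
(`unscale_panel()`).

## Priors

* **Variance components** (trait, wave-1 trait, disturbance, and state
  variances): inverse gamma in the prior-sample-size form — prior sample
  size $\nu_\phi$ and prior variance location $\sigma_0^2$ map to
  $IG(\nu_\phi/2,\; \nu_\phi\sigma_0^2/2)$ (shape, rate). The default
  $\nu_\phi = 1, \sigma_0^2 = 1/3$ gives $IG(0.5, 1/6)$, whose prior mode
  for a variance is $1/9$ — weakly informative on the scaled metric where
  each total variance is near 1. The sensitivity alternative
  $\nu_\phi = 3$ gives $IG(1.5, 0.5)$
  (`sensitivity_refit()`).
* **Regression coefficients** (carryover, spillover, covariate effects):
  $N(0, 1)$, expressing that standardized-metric coefficients plausibly lie
  in $(-1, 1)$.
* **Correlation-type parameters**: each covariance block is parameterized
  as (variances, correlation) with the correlation uniform on $(-1, 1)$.
  This is a concrete, declared stand-in for generic software-default
  diffuse priors; the equated state covariance is parameterized as a
  fraction (uniform on $(-1,1)$) of its tightest positive-definiteness
  bound $\sqrt{\min_t s_{EM,t} \min_t s_{CL,t}}$, which guarantees every
  wave's state block stays positive definite.
* **Exogenous covariate variances** (conditional model): diffuse conjugate
  $IG(0.01, 0.01)$.

## Posterior sampling

Sampling runs on an unconstrained scale — log variances, atanh of the
correlation-fraction parameters, identity on coefficients — with the exact
Jacobian terms, so every draw maps back to a valid parameter set by
construction.

The kernel is preconditioned Hamiltonian Monte Carlo:

1. a BFGS search with the analytic gradient finds the posterior mode, and
   the inverse Hessian seeds the mass matrix (Laplace metric);
2. during burn-in the step size is tuned by dual averaging toward a target
   acceptance of 0.8, and the metric is refreshed twice from pilot draws
   (estimates shrunk toward the current metric, weight $m/(m+100)$ for a
   window of $m$ draws, for stability);
3. after burn-in the kernel is frozen; the leapfrog path length is
   jittered uniformly on $1..L_{max}$ ($L_{max} = 24$ by default).

The gradient of the marginal log-likelihood is analytic: for any parameter
$\phi$, $\partial \ell = -\tfrac12\,\mathrm{tr}(W\, \partial\Sigma/\partial\phi)$
with $W = \sum_p n_p(\Sigma_{oo}^{-1} - \Sigma_{oo}^{-1} M_p \Sigma_{oo}^{-1})$
accumulated over missingness patterns, and $\partial\Sigma/\partial\phi$
obtained by differentiating the VAR recursion. The hot path (implied
covariance, pattern-wise likelihood, gradient contraction) is implemented
in C++; an independent R implementation of the likelihood is kept as the
reference path and the two are tested for equality.

Defaults mirror the motivating protocol: 3 chains, 1000 burn-in and 1000
saved draws per chain. Convergence gates: split-chain PSR below 1.05
(1.1 is a warning level) and ESS of at least 300, computed per parameter
(`psr_report()`); a failing fit is returned flagged with a warning, never
silently. Within-chain draws are deterministic given the root seed.

An honest note on difficulty: the 26-dimensional posterior is a curved
ridge in the directions that trade wave-1 trait variance against carryover
and interval-1 spillover (those parameters are weakly identified — their
posterior SDs are an order of magnitude larger than the rest, and their
marginals are strongly skewed). Independence-style Metropolis–Hastings
proposals fail badly here, which is why the sampler is gradient-based.
A practical consequence for simulation studies: the *posterior mean* of an
interval-1 cross-lag can sit 0.1–0.4 from the generating value even when
the (wide, asymmetric) credible interval covers it comfortably; this is a
feature of the information geometry at $n \approx 7{,}500$, not an
estimation defect, and it matches the asymmetric intervals reported for
those same rows in the motivating analysis.

## Standardization

`starts_standardize()` reports the conventional standardized solution:
trait loadings $\lambda_{CST,x,t} = sd(CST_x)/sd(Y_{x,t})$ and
$\lambda_{ART,x,t} = sd(ART_{x,t})/sd(Y_{x,t})$ with $sd(Y_{x,t})$ from the
implied covariance diagonal; standardized paths
$\beta\,sd(\text{predictor})/sd(\text{outcome})$ using the implied latent
trait SDs at the relevant waves; and correlations for every covariance
parameter. Posterior summaries standardize per draw and then average; the
value obtained by standardizing the posterior mean is reported alongside,
since the two differ by a Jensen gap.

## Bayesian fit indices

The package uses a posterior-discrepancy construction of the approximate
and noncentrality indices. Per draw $i$,
$D_i = -2(\ell(\theta_i) - \ell_{sat})$ against the saturated
(unstructured mean and covariance) maximum ($\ell_{sat}$ is closed-form for
complete data and computed by an EM algorithm under missingness);
$p_D = \overline D - D(\bar\theta)$ is a DIC-style effective parameter
count; $df = p^* - p_D$ with $p^* = 36$ modeled moments (44 when means are
modeled); and the per-draw noncentrality is $nc_i = D_i - p_D - df$. Then

* $BRMSEA_i = \sqrt{\max(0, nc_i / (df\,(N-1)))}$,
* $BCFI_i = 1 - \max(0, nc_i)/\max(nc_{0,i}, nc_i, 0)$,
* $BTLI$ from the standard TLI formula on $(D - p_D, df)$ pairs,
* $BGamma\hat{}_i = p/(p + 2\,nc_i/(N-1))$ with $p = 8$,
* $BMc_i = \exp(-0.5\,nc_i/(N-1))$,

with the null model (independence, free variances, means at the sample
mean) supplying $nc_{0,i}$; because that null model is conjugate under the
inverse-gamma priors, its posterior is sampled exactly rather than by
MCMC. Posterior means and 90% intervals are reported. The construction is
a methodological reconstruction of indices that are named but not defined
in most applied reports; it is validated by threshold behaviour (a
correctly specified model at cohort scale earns $BCFI \approx 1.00$ and
$BRMSEA < 0.01$; omitting real cross-construct structure demonstrably
worsens both), not by exact numerical equality with any one software
implementation.

## The printed-tables back-out and the synthetic cohort

Because the cohort micro-data are access-restricted, the package
reconstructs a complete generating parameter set from the published
summary tables alone (`backout_params()`):

1. scaled wave variances $v_{x,t} = (SD_{x,t}/\overline{SD}_x)^2$ from the
   descriptive table;
2. stable-trait variances as the across-wave mean of
   $\lambda_{CST,x,t}^2 v_{x,t}$ — the model says these are time-invariant,
   so the spread of the per-wave values (coefficient of variation 1.6% for
   EM, 3.5% for CL, the latter driven by the wave-4 printed loading) is
   itself the internal-consistency check;
3. wave-1 trait variances from the wave-1 loadings, with the printed raw
   covariance (0.113);
4. disturbance variances backed out at the first interval so the implied
   wave-2 trait variances match the wave-2 loadings, then held equated
   (printed covariance 0.045); the small late-wave discrepancies this
   leaves (printed rounding) are absorbed into the state variances so the
   total wave variances are matched exactly;
5. state variances as the per-wave remainder, with the printed equated
   state covariance (-0.065).

Feeding this set back through `starts_standardize()` reproduces the
published standardized column within ±0.01 on 20 of its 22 rows. The two
exceptions are genuine internal inconsistencies of the printed tables at
that precision: the stable-trait correlation comes out -0.583 against a
printed -0.572 (the loadings-implied trait variances are ~3% smaller than
the fitted model's), and the wave-4 state correlation comes out -0.213
against a printed -0.180 (no parameter set satisfying the back-out
arithmetic can reach it). The acceptance tests assert all 22 rows and
leave those two red deliberately, as a measurement of that inconsistency.

`generate_cohort()` then simulates dyads on the scaled metric,
inverse-scales to the raw composite metric using the printed wave means
and average SDs, optionally discretizes to the instrument ranges (EM
integers 0–10, CL integers 7–35), applies whole-wave attrition (cohort
entry at wave 1 is always observed; the default rates emulate the
published wave sizes 9,793 / 9,001 / 5,344 / 8,032, and a
missing-at-random variant makes dropout logistic in the observed wave-1
EM score), and draws six covariates with marginals matching the published
sample description (49.67% female; 84.25% ethnic-majority caregivers;
income deciles, household type, and two ill-health ordinals as rounded
clipped normals matching the printed means and SDs). The printed closeness
means (33.805 etc. on a 7–35 scale) sit implausibly close to the scale
maximum; they are reproduced verbatim as defaults and are configurable.

What the generator deliberately does *not* emulate: item-level response
processes (composites are drawn directly from the latent-Gaussian model),
survey weights and household clustering, and any informative missingness
beyond the wave-1-score mechanism. Passing tests therefore certify the
estimation machinery on data generated by the model itself (plus
discretization and attrition), not robustness to real-world violations of
the STARTS structure.

## Covariate-conditional model

For the robustness check, the six covariates enter as standardized
exogenous predictors of all eight observed variables with time-invariant
(equated) coefficients — one coefficient per covariate per construct.
Covariates are modeled as independent normals with free variances under
the diffuse conjugate prior, so dyads with missing covariate values are
marginalized by the same pattern-wise likelihood instead of being dropped.
The joint implied covariance is
$\begin{pmatrix}\Sigma + \Gamma S_x \Gamma' & \Gamma S_x\\ S_x\Gamma' & S_x\end{pmatrix}$
with $\Gamma$ the structured coefficient matrix. The independence working
model for the covariates is a simplification (the real covariates are
mildly correlated, average VIF 1.44); it affects only the exogenous block,
not the structural parameters, when covariates are complete.

## Numerical choices and degenerate inputs

* Variances are sampled as logs with a cap at $e^{50}$; correlations as
  atanh with the prior on the correlation scale (the Jacobian keeps the
  implied prior uniform).
* The state-covariance bound uses the minimum state variances per
  construct; its derivative is taken at the active minimum (ties have
  measure zero).
* `validate_starts_params()` collects violations rather than throwing;
  fitting and simulation refuse invalid sets with the offending block
  named. Composite scoring treats any missing item as a missing composite
  (no proration). Pairwise-complete correlations are used for
  descriptives, which is what makes an $n = 7{,}507$ correlation matrix
  with wave attrition reportable; VIF is computed from the inverse of the
  covariate correlation matrix and capped (with a flag) under perfect
  collinearity.
* All randomness flows through explicit integer seeds; a pipeline run
  derives per-stage seeds deterministically from a single root seed.

## Problem sizes used in the checks

The test-suite experiments are sized for a desktop run: Monte-Carlo
validation of the implied moments uses $10^6$ simulated dyads (agreement
within 3 Monte-Carlo standard errors, every entry); paper-protocol fits
run at the cohort size $n = 7{,}507$ with the full 3 × (1000 + 1000)
protocol; credible-interval calibration uses 100 replicates of the
17-parameter structural submodel (state block fixed at its generating
values) at $n = 400$ with 2 × (250 + 250) draws, pooling coverage across
the structural parameters; the conjugate single-variance check compares
4,500 thinned draws against the exact inverse-gamma posterior by a
Kolmogorov–Smirnov test at $\alpha = 0.01$.

## Known limitations

* Two constructs only; the wave count is general in the recursion but the
  package is exercised and tested at $T = 4$.
* No latent growth components, no item-level measurement model, no
  survey-design features.
* The fit-index construction is a reconstruction (above), suitable for
  threshold judgements rather than cross-software numerical comparison.
* Posterior means of weakly identified interval-1 spillover parameters are
  skew-dominated at realistic sample sizes; report credible intervals, not
  point estimates, for those rows.
* Model comparison (information criteria, posterior predictive checks) is
  out of scope.
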