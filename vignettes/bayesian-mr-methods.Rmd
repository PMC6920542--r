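---
title: "Bayesian Mendelian randomization with pleiotropic instruments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Mendelian randomization with pleiotropic instruments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmr)
```

## The problem

Mendelian randomization (MR) estimates the causal effect of an exposure $X$
on an outcome $Y$ from observational data by using genetic variants
$Z_1, \dots, Z_J$ (allele doses 0/1/2) as instruments. An instrument is
valid if it is associated with the exposure, independent of the unobserved
exposure–outcome confounders, and affects the outcome only through the
exposure. The last condition — no *pleiotropy* — is untestable and often
false when many variants are used. `bayesmr` implements a one-sample
Bayesian model in which every instrument is allowed a direct (pleiotropic)
effect on the outcome, with a shrinkage prior expressing the belief that an
unspecified subset of these effects is zero.

## The single-exposure model

With a standardized latent confounder $U \sim N(0,1)$:

$$X \mid Z, U \sim N\!\big(\omega_X + \textstyle\sum_j \alpha_j Z_j + \delta_X U,\ \sigma_X^2\big), \qquad
Y \mid X, Z, U \sim N\!\big(\omega_Y + \theta X + \textstyle\sum_j \beta_j Z_j + \delta_Y U,\ \sigma_Y^2\big).$$

$\theta$ is the causal effect of interest, $\alpha_j$ the instrument
strengths, $\beta_j$ the pleiotropic effects. Marginalizing $U$
analytically, $(X, Y)\mid Z$ is bivariate normal with error covariance
$$\Sigma = \begin{pmatrix} \tau_X^2 & \lambda \\ \lambda & \tau_Y^2 \end{pmatrix},
\qquad \tau_X^2 = \delta_X^2 + \sigma_X^2,\quad
\tau_Y^2 = \delta_Y^2 + \sigma_Y^2,\quad \lambda = \delta_X\delta_Y.$$
The sampler targets this marginalized form (`fit_single_exposure()`); no
per-individual latent variable is ever sampled. The identity between the
two formulations is enforced by a unit test that integrates $U$ out by
numerical quadrature on a small dataset.

The model is not likelihood-identified: the data cannot distinguish
$(\theta, \beta, \lambda)$ from
$(\theta + \lambda/\tau_X^2,\ \beta - \alpha\lambda/\tau_X^2,\ 0)$ and the
family of states in between. Identification comes from the prior on
$\beta$: if an unspecified subset of pleiotropic effects is exactly or
nearly zero, the shrinkage prior concentrates the posterior along the
equivalence class, and $\theta$ acquires a proper posterior.

### Priors

* `beta_prior = "horseshoe"` (default): $\beta_j \mid \phi_j \sim N(0, \phi_j^2)$,
  $\phi_j \sim \mathrm{Cauchy}^+(0, \gamma)$, $\gamma \sim \mathrm{Cauchy}^+(0,1)$.
  The shrinkage weight $\kappa_j = 1/(1+\phi_j^2)$ has a Beta(1/2, 1/2) prior
  law when $\gamma = 1$: mass piles up near 1 (effect shrunk to zero) and
  near 0 (effect left alone), which is exactly the "some instruments are
  pleiotropic, most are not" belief.
* `beta_prior = "laplace"`: double-exponential with variance $2\tau^2$,
  $\tau \sim \mathrm{Cauchy}^+(0,1)$.
* `beta_prior = "point_zero"`: $\beta \equiv 0$, the classical IV analysis;
  useful as a fully identified reference.

Instrument strengths get a hierarchical $\alpha_j \sim N(\mu_\alpha,
\sigma_\alpha^2)$ prior with flat hyperpriors (requires $J \ge 2$; scalar
instrument sets fall back to a fixed $N(0, 10^2)$ prior). $\theta$,
intercepts and loadings are flat; $\sigma_X, \sigma_Y$ flat on the positive
half-line. Optional bounds (`u_tau_x2`, `theta_bounds`) restrict the
support when external information warrants it. The pleiotropy prior is
independent of the exposure-model parameters — the Bayesian version of the
InSIDE ("instrument strength independent of direct effect") assumption.

No recoding of allele directions is performed anywhere in the Bayesian
model; the Egger comparator recodes internally, as that estimator requires.

### Sampling

The posterior is explored by a blocked Gibbs sampler (RcppArmadillo):

1. $(\omega_X, \alpha)$ and $(\omega_Y, \theta, \beta)$ are conditionally
   Gaussian given the error covariance — sampled exactly from their
   precision systems. All conditionals reduce to Gram-matrix algebra after
   one $O(np^2)$ pass, so a sweep costs $O(p^3)$ regardless of $n$.
2. The half-Cauchy scales of the horseshoe and Laplace hierarchies are
   sampled through the standard inverse-gamma / inverse-Gaussian parameter
   expansions, keeping every update conjugate.
3. $(\delta_X, \delta_Y, \sigma_X, \sigma_Y)$ move by an adaptive
   random-walk Metropolis step (log scale for the $\sigma$'s, flat priors on
   the natural scale via Jacobian terms).
4. A second, *compensated* Metropolis kernel proposes the same block but
   simultaneously shifts $(\theta, \omega_Y, \beta)$ along the
   observational-equivalence direction
   $\theta \to \theta - \Delta\rho$, $\beta \to \beta + \Delta\rho\,\alpha$
   with $\rho = \lambda/\tau_X^2$. Along this direction the likelihood is
   (near-)invariant and only the shrinkage prior discriminates — without
   this move the two-block Gibbs walk crosses the ridge in tiny steps and
   mixes impractically slowly. Acceptance uses the exact marginal
   likelihood (sufficient statistics), so the kernel remains valid even
   when parts of the compensation are unavailable (e.g. under
   `point_zero`).
5. Two likelihood-invariant moves handle the internal non-identifiability
   of the loadings themselves: a rescaling $(\delta_X, \delta_Y) \to
   (c\,\delta_X, \delta_Y/c)$ at fixed $(\tau_X^2, \tau_Y^2, \lambda)$, and
   a joint sign flip.

Defaults are 4 chains of 1000 warmup + 1000 kept sweeps; adaptation (step
sizes, Robbins–Monro toward 30% acceptance) happens only during warmup.
Convergence is reported as split-$\hat R$ and effective sample size per
parameter; $\hat R > 1.05$ on a causal parameter raises a flag on the fit
(never an error). There is no divergence diagnostic because no gradient
integrator is involved; the Metropolis acceptance rates are reported
instead.

### Covariate interaction

With a binary covariate $W$ (e.g. sex), `fit_single_exposure()` extends the
mean structure to
$\omega_X + \alpha'Z + \psi_{XW} W$ and
$\omega_Y + (\theta + \psi_{YXW} W)X + \beta'Z + \psi_{YW} W$, so the causal
effect is $\theta$ at $W=0$ and $\theta + \psi_{YXW}$ at $W=1$. The
stratum effect is summarized draw-wise, e.g.
`summarize_posterior(fit, "theta + psi_YXW")`.

## Two exposures and mediation

`fit_mediation()` elaborates the model to exposures $X_1 \to X_2$ with
non-overlapping, mutually independent instrument sets $I_1$ (strengths
$\alpha_1$ on $X_1$) and $I_2$ (strengths $\alpha_2$ on $X_2$, plus
cross-associations $\alpha_3$ with $X_1$), pleiotropic vectors $\beta_1,
\beta_2$ (on $Y$) and $\beta_3$ ($I_1$ on $X_2$), and a shared confounder
loading $(\delta_1, \delta_2, \delta_3)$ — giving error covariance
$\delta\delta' + \mathrm{diag}(\sigma^2)$. The direct effect of $X_1$ on
$Y$ is $\theta_1$, the mediated chain is $\theta_2$ ($X_1 \to X_2$) and
$\theta_3$ ($X_2 \to Y$); `derived_effects()` reports direct, indirect
($\theta_2\theta_3$) and total ($\theta_1 + \theta_2\theta_3$) effects
evaluated draw by draw.

When all pleiotropic vectors vanish and instruments are scalar, the model
is identified in closed form by path tracing on standardized variables:
$\rho_{X_1I_1} = \alpha_1$, $\rho_{X_1I_2} = \alpha_3$, then a triangular
sequence of $2\times 2$ systems whose determinants are $\alpha_1$ and
$\alpha_1\alpha_2$ (the two relevance conditions). The package implements
this solver (`moment_solve_no_pleiotropy()`, data interface
`mediation_moment_estimates()`) and uses it as an independent oracle for
the posterior fit. The sequential-relevance condition is screened by
conditional regressions (`sequential_relevance()`); a violated condition is
*reported* on the fit, never used to drop instruments automatically.

The mediation sampler mirrors the single-exposure one in plain R (the
designs are small once the Gram matrix is precomputed), with compensated
covariance moves per equation. Mixing is genuinely slow in this model —
the decomposition of a well-identified total effect into direct and
indirect parts is weakly identified — and long chains (thousands of
sweeps, several chains) are the recommended practice; the split-$\hat R$
flags make insufficient runs visible.

## Frequentist comparators

* `per_instrument_associations()` — marginal OLS slopes and SEs of $X$ and
  $Y$ on each instrument (closed form, matching `lm`).
* Ratio estimates $\hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
  inverse-variance weights $\hat\beta_{Xj}^2/se_{Yj}^2$.
* `weighted_median()` — the interpolated weighted median: sorted values,
  standardized mid-cumulative weights $p_j = (S_{j-1} + w_j/2)/S_J$, linear
  interpolation at $p = 1/2$. Consistent when at least half the weight lies
  on valid instruments. `wme_with_ci()` adds a nonparametric percentile
  bootstrap over individuals (default 1000 resamples), recomputing the full
  pipeline per resample; degenerate resamples (a constant dose column) are
  redrawn and counted.
* `egger_regression()` — weighted least squares of outcome on exposure
  associations after jointly flipping pairs with negative
  $\hat\beta_{Xj}$; slope = causal estimate, intercept = average
  directional pleiotropy; $t$ intervals with $J-2$ df.

## The synthetic-data generator

Real genotype panels are emulated, not ingested. `simulate_genotypes()`
draws a latent $J$-vector from a single-factor Gaussian copula with
exchangeable correlation and double-thresholds each coordinate at its
Hardy–Weinberg quantiles, so each column is marginally HWE at its
minor-allele frequency and the pairwise dose correlation is controlled by
the latent correlation. The latent correlation is calibrated to the target
mean pairwise $r^2$ analytically (bivariate-normal rectangle probabilities
by one-dimensional quadrature, then monotone root finding) — deterministic,
with no simulation noise in the calibration itself. MAFs default to
$U(0.1, 0.4)$; the real MAF spectrum behind the reference benchmarks is
unknown, and this choice is exposed as an argument. The generator does not
model population structure, haplotype phase, or realistic local LD decay —
only the *average* pairwise $r^2$ that the benchmark scenarios vary.

`table1_scenario()` encodes the 21 benchmark scenarios (sample size, mean
pleiotropy, instrument-strength dispersion, instrument count, LD level).
Structural parameters are redrawn per replicate:
$\alpha_j \sim N(-0.07, \sigma_\alpha^2)$; a random 40% of instruments get
$\beta_j \sim N(\mu_\beta, 0.05^2)$ (scenarios 1–13) or *all* instruments
get $\beta_j \sim N(\phi, 0.05^2)$ with $\phi \sim U(-0.012, 0.012)$ per
replicate and 80% of the $\alpha_j$ zeroed (scenarios 14–21);
$\omega_X \sim N(3.3, 0.2^2)$, $\omega_Y \sim N(0.9, 0.2^2)$,
$\delta_X, \delta_Y \sim N(-0.1, 0.02^2)$; $\sigma_X, \sigma_Y$ from sharp
inverse-gamma laws (shape 50) with means 0.1 and 0.3 *on the SD scale* —
the benchmark description does not fix the scale (SD vs. variance) or the
sharpness, and these choices are exposed as arguments. One genotype matrix
is drawn per scenario and reused across replicates (a flag allows
redrawing).

What passing the replication tests shows, and what it does not: the
generator reproduces the *stated* benchmark conditions, but unstated ones
(the MAF spectrum of the original SNP panels, the inverse-gamma scale)
remain choices. In replication runs these choices reproduce the published
coverage columns closely while producing systematically higher power in
the weak-instrument scenario for *both* methods, a pattern consistent with
the emulated instruments being somewhat stronger than the originals rather
than with an estimator defect.

## The replication harness

`evaluate_scenario()` replays a scenario: per regime ($\theta = 0$ and
$\theta = 0.35$) and replicate it redraws parameters, simulates data, runs
each estimator adapter and aggregates coverage under the null (% of
nominal-95% intervals containing 0), coverage under the alternative (%
containing 0.35), power (% excluding 0 under the alternative) and bias
(mean of point minus truth), with binomial Monte-Carlo SEs. Intervals are
closed; the Bayesian point estimate is the posterior mean. Everything is
reproducible from one master seed (per-replicate child seeds are drawn
up-front); method failures are excluded from that method's aggregates and
counted.

Problem sizes used by the shipped checks: the weighted-median benchmarks
run at the full 800 replicates per regime; the Bayesian benchmarks run at
100 replicates per regime with 2 chains of 500+500 sweeps (the full
800-replicate Bayesian grid is a long-running mode, not the default);
recovery checks use single datasets of $n$ = 2000–5000 (the mediation
recovery runs 4 chains of 8000+8000 sweeps, reflecting its slow mixing)
and one $n = 10^5$ moment-oracle comparison.

## Numerical choices and edge cases

* Conjugate draws add a $10^{-10}$-scaled jitter to precision diagonals
  before Cholesky.
* Metropolis step sizes adapt only during warmup ($t^{-0.6}$ decay toward
  30% acceptance), so the post-warmup kernels are fixed.
* Initial values come from least squares with 10% relative jitter per
  chain; `init_jitter` can be raised for overdispersed starts.
* Zero-variance dose columns are an error in model fits and are excluded
  (with a warning) from $r^2$ summaries; bootstrap resamples that produce
  one are redrawn and counted.
* The weighted median returns the boundary value when half the total
  weight sits on an extreme observation; ties are handled by the sorted
  interpolation itself.
* `sigma_alpha` updates need $J \ge 2$; scalar sets use the fixed wide
  normal.

## Known limitations

* One-sample, individual-level, continuous-trait data only; no
  summary-statistic Bayesian model (the frequentist comparators do accept
  summary tables).
* The mediation model supports exactly two exposures and no
  exposure–mediator interaction.
* Slow mixing of the mediation decomposition at small instrument counts is
  inherent to its prior-driven identification; budget long chains.
* The genotype generator controls only average pairwise LD, not realistic
  block structure.
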