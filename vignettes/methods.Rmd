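---
title: "Screening predictive laboratory analytes from sparse hospital matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening predictive laboratory analytes from sparse hospital matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Routine hospital laboratory data form a very sparse case-by-analyte matrix:
every patient gets an individual set of tests, so most cells were simply
never measured. `labsieve` asks, for a binary diagnosis derived from ICD-10
codes (the motivating case is myocardial ischemia, categories I20–I25,
labelled 1 when any diagnosis code falls in that range), which analytes are
*predictive* — not by fitting one model, but by averaging over all subsets
of analytes and reporting each analyte's posterior probability of appearing
in the model.

The pipeline is: restrict the cohort to cases with a measured index analyte
(troponin T, the analyte any suspected myocardial ischemia work-up
includes, so it is fully observed by construction); build nested
sparsity-tiered analyte subsets; complete each tier by multiple imputation;
run Bayesian model averaging over probit models on every completed dataset;
pool the per-analyte posterior inclusion probabilities across imputation
chains; and flag analytes at or above 95% pooled inclusion as highly
predictive.

## The model

For cases $i = 1,\dots,n$ with standardized analyte values
$x_i \in \mathbb{R}^p$ and binary diagnosis $y_i$, each model is indexed by
an inclusion vector $\gamma \in \{0,1\}^p$:

$$\Pr(y_i = 1 \mid \gamma, \alpha, \beta) =
  \Phi\!\left(\alpha + x_{i,\gamma}^\top \beta_\gamma\right),$$

with independent Bernoulli($\pi$) priors on the $\gamma_j$ (default
$\pi = 1/2$), a normal slab $\beta_j \sim N(0, \tau^2)$ on included
standardized coefficients (default $\tau^2 = 1$), and a vague normal
intercept ($\mathrm{Var} = 10^6$). The quantity of interest is the
posterior inclusion probability
$\rho_j = \Pr(\gamma_j = 1 \mid y)$, averaged over the whole $2^p$ model
space. No prior is placed on which analytes "should" matter; the model-size
penalty emerges from the marginal likelihood itself (the built-in Occam
effect), which is also why pure-noise analytes end up *below* the prior
$\pi = 1/2$ rather than at it.

### Orthogonal data augmentation

A Gibbs sampler over $(\gamma, \beta)$ mixes poorly when analytes are
correlated. We therefore augment the standardized design $X_o$ with $p$
pseudo-rows $X_a$ chosen so that the combined Gram matrix is diagonal:

$$X_o^\top X_o + X_a^\top X_a = \mathrm{diag}(D), \qquad
  D = (\lambda_{\max}(X_o^\top X_o) + \varepsilon)\,\mathbf{1}_p,$$

with $X_a$ the upper-triangular Cholesky factor of
$\mathrm{diag}(D) - X_o^\top X_o$, which is positive definite by
construction (its smallest eigenvalue is $\varepsilon$; default
$\varepsilon = 0.001\,\lambda_{\max}$, the smallest uniform inflation that
keeps the factorization comfortably away from singularity). Because the
columns of $X_o$ are centred and the augmented rows carry no intercept, the
intercept decouples as well.

Each Gibbs iteration then draws: (1) latent probit utilities
$Z_{o,i} \sim N(\alpha + x_i^\top\beta, 1)$ truncated to the half-line
fixed by $y_i$; (2) augmented responses $Z_a \sim N(X_a \beta, I)$;
(3) per-coordinate complete-data estimates
$\hat\beta_j = (X^\top Z)_j / d_j$, which are conditionally independent
because the complete Gram matrix is diagonal; (4) each $\gamma_j$ from a
Bernoulli with probability

$$\rho_j^{(t)} = \frac{\pi\, N(\hat\beta_j;\, 0,\, 1/d_j + \tau^2)}
  {\pi\, N(\hat\beta_j;\, 0,\, 1/d_j + \tau^2) +
   (1-\pi)\, N(\hat\beta_j;\, 0,\, 1/d_j)},$$

then $\beta_j$ from its conjugate normal (a point mass at zero when
$\gamma_j = 0$), and the intercept from its normal conditional. The
reported $\rho_j$ is the *Rao-Blackwellized* average of the
$\rho_j^{(t)}$ over post-burn-in iterations, which has visibly lower
Monte-Carlo variance than the raw frequency of $\gamma_j = 1$ (this is
asserted as a test). Defaults: 20,000 iterations, 5,000 burn-in. Model
visit counts are retained, so an Occam's-window pruning of the visited
model list (keep models within a factor $C$ of the best) is available as a
secondary output.

### Why the sampler can be trusted

The package carries its own independent oracle. For a real-valued outcome
the marginal likelihood of every model is Gaussian and available in closed
form, so `enumerate_linear()` evaluates all $2^p$ models exactly
($p \le 12$); for the probit link, `enumerate_probit_quadrature()`
integrates the likelihood against the priors by Gauss–Hermite quadrature
adapted at each model's posterior mode with Hessian rescaling
($p \le 3$, giving at most a 4-dimensional integral). Both oracles consume
the same prior object as the sampler, so a disagreement can only implicate
the sampler. The quadrature refines its node count once and requires the
two log-marginal estimates to agree to $10^{-4}$ — far below the
$\pm 0.02$ agreement band the oracle serves, and affordable within the
quadrature's evaluation budget at $n$ up to 2000. The acceptance suite
checks sampler-versus-oracle agreement within $\pm 0.02$ per analyte over
20 random linear instances ($p \le 10$, $n = 300$) and probit instances at
$p = 1, 2, 3$.

## Multiple imputation

Each sparsity tier (analytes missing in at most 20/40/60/80% of cases;
boundaries inclusive, so the tiers are nested and the index analyte is in
every tier) is completed by chained-equation imputation: missing cells are
initialized by draws from each analyte's observed empirical distribution,
then each sweep revisits the incomplete analytes in descending-coverage
order and redraws their missing cells from the posterior predictive of a
ridge-stabilized Bayesian linear regression (ridge
$10^{-6} \cdot \mathrm{tr}(X^\top X)/p$, inflated $10^4$-fold on a
singularity warning) on all other currently-completed analytes *plus the
diagnosis label* — excluding the outcome from imputation models would bias
the imputed associations toward null. Strictly positive analytes whose IQR
exceeds their median are modelled on the log scale, a rule that catches
heavily right-skewed laboratory quantities (troponin, CK, bilirubin) while
leaving near-symmetric ones (electrolytes, red-cell indices) untouched.

Two design choices deserve explanation because the obvious defaults fail:

* **Collinearity guard.** A derived analyte such as CKD-EPI eGFR is an
  (almost) deterministic function of its parent creatinine. If each is
  allowed to impute the other, the jointly missing cells of a case
  random-walk along the shared curve: the pair's sweep-to-sweep
  autocorrelation time reaches several sweeps and the between-chain
  variance of the monitored statistic stays inflated at any window. As in
  standard chained-equation practice, the cycle is broken one-directionally:
  when two incomplete analytes correlate above 0.8 (absolute, working
  scale, jointly observed cells), the later-visited one is dropped from the
  earlier one's predictor set while the reverse direction is kept, so the
  derived analyte still follows its parent. The 0.8 default is deliberate:
  analyte pairs above it in laboratory panels are almost always
  analytically coupled (calculated quantities), while genuine biological
  correlations sit well below.

* **Monitoring window.** Convergence is monitored per analyte by the mean
  of its imputed cells per sweep, across M = 5 independently initialized
  chains, with the Gelman–Rubin statistic
  $\hat R = \sqrt{\hat V / W}$, $\hat V = \frac{n-1}{n} W + B/n$, computed
  on the second half of the trajectory. The statistic itself is noisy on
  short windows: with a 10-point window and five chains, spurious
  $\hat R > 1.1$ excursions are common on visibly stationary trajectories
  simply because the monitored mean carries a 1–4 sweep autocorrelation.
  The defaults are therefore 60 sweeps with $\hat R$ on the last 30, which
  keeps the maximum $\hat R$ across the default panel's 27 incomplete
  analytes at about 1.03–1.06. Convergence is declared below the
  conventional 1.1. Degenerate cases are flagged rather than silently
  numeric: identical constant chains ($W = B = 0$) report `NA`, divergent
  constant chains ($W = 0, B > 0$) report `Inf`.

The sampler runs once per completed dataset (never on a pooled completion),
and the M chain-specific $\rho_j$ are pooled as their mean with a normal
approximation interval $\bar\rho \pm 1.96\, s/\sqrt{M}$ truncated to
$[0,1]$. A percentile interval would be degenerate at M = 5, hence the
normal approximation. When the chains agree exactly — the typical case for
the index analyte at 100% inclusion — no interval is reported, and the
cross-tier table counts an analyte's flags only in the tiers it belongs to,
displaying "-" (not 0) elsewhere.

## The synthetic cohort

Real hospital extracts cannot be shared, so the generator stands in for
them with the statistical structure the method actually relies on:

* **Skewed marginals.** Each analyte draws a latent standard normal
  $z_j = \ell_j s + \sqrt{1-\ell_j^2}\,\epsilon_j$, where $s$ is a shared
  per-case severity factor — the simplest correlation structure that makes
  imputation non-trivial. Lognormal analytes set the log-median to
  $\log(m)$ and solve the log-sd from the IQR/median ratio
  ($\sigma = \mathrm{asinh}(\mathrm{IQR}/2m)/z_{0.75}$), matching the heavy
  right skew of routine laboratory values; normal analytes use
  $m + \mathrm{IQR}/1.349 \cdot z$; the arterial/venous collection-type
  analyte thresholds its latent normal at a 25% arterial rate.
* **Outcome.** A probit link on the standardized latents of the true
  predictors, with the intercept solved numerically for the prevalence
  target. The default panel has ~28 analytes named after routine emergency
  laboratory quantities with realistic median/IQR targets, three non-zero
  standardized coefficients (troponin analog 2.0 — dominant by design,
  potassium 0.8, urea 0.5) and the remainder null. Default prevalence is
  0.1 rather than the few-percent rate of a real emergency cohort: at
  desk-scale n the higher rate keeps enough positive cases for recovery
  tests to have power, and the prevalence is a configuration field, not a
  constant.
* **Missingness.** MCAR analytes hide cells independently at rate
  1 − coverage; MAR analytes hide with probability logistic in the latent
  severity (unit slope, intercept solved for the marginal rate), so
  sicker cases are *more* likely to be measured or less, detectably
  different from MCAR by a KS test at n = 10,000 (asserted). Coverage
  targets are spread over the four bands so tiering the cohort reproduces
  the nested-subset structure. The troponin analog is never hidden.
* **Derived analyte.** eGFR is computed from creatinine, age and sex by the
  CKD-EPI equation exactly as printed, and inherits creatinine's mask. Note
  that the equation's own widely circulated worked example (female, 53 y,
  serum creatinine 0.8 mg/dL) evaluates to ≈ 84.2 mL/min/1.73 m², not the
  88 sometimes quoted next to it; the implementation follows the formula
  and the tests pin the 84.2.

What the generator does *not* emulate: real analyte-specific measurement
error, informative missingness depending on the hidden value itself (MNAR),
multi-visit time structure, or the full covariance of a real laboratory
panel. Passing tests therefore demonstrate the machinery — imputation that
respects the data-generating regressions, a sampler that matches exact
enumeration, correct pooling and classification — not clinical validity on
any real cohort.

## Numerical choices and degenerate inputs

* Standardization is exact (columns recentred/rescaled; zero-variance
  columns are an error naming the analyte).
* The augmentation retries once with a 10-fold $\varepsilon$ before
  failing; the completed Gram matrix must match $\mathrm{diag}(D)$ within
  $10^{-8} \max(D)$ (asserted up to $p = 110$, the widest tier the
  motivating study reports).
* Truncated-normal draws use inverse-CDF in the upper tail, switching to a
  log-space path under deep truncation, so extreme linear predictors do not
  produce infinite utilities.
* Ties in the imputation visit order are broken by analyte id; duplicate
  measurements default to first-by-timestamp (the presentation value is
  the diagnostically relevant one — the reduction policy is configurable
  because source systems differ).
* ICD-10 matching is by three-character category, closed interval, after
  upper-casing and whitespace stripping; malformed codes warn and never
  match. Mixed units within an analyte are an error, never a silent
  conversion.
* Empty inputs degrade explicitly: an empty records file parses to an
  empty record set; a cohort with no measured index analyte returns an
  empty matrix with a warning; a tier retaining no analyte is an error.

## Problem sizes

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path at meaningful power: cohorts of n = 2000 (10,000 for
missingness-rate checks), panels of 20–28 analytes, 5 imputation chains of
60 sweeps, 20,000-iteration sampler runs, oracle comparisons at
$p \le 10$ (linear) and $p \le 3$ (probit), and 10-seed replications for
the recovery and calibration properties. The headline numbers of the
motivating study (hundreds of thousands of cases, 1929 analytes) are not
reproducible without its non-shared hospital data and serve only as
documentation of scale.

## Known limitations

* Predictive mean matching, overimputation/measurement-error modelling and
  multilevel imputation are out of scope; imputation assumes (log-)linear
  conditional models.
* The probit oracle is limited to $p \le 3$ by quadrature dimension; the
  sampler itself has no such limit.
* Occam's-window output is estimated from model visit counts, so models
  never visited in 15,000 post-burn draws are absent by construction.
* Ridge/Lasso-regularized model search is deliberately not implemented.
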