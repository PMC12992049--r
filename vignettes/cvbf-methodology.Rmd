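---
title: "Cross-validated Bayes factors for longitudinal mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated Bayes factors for longitudinal mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvbflmm)
```

## The scientific problem

Observational memory-clinic cohorts are used to ask whether a baseline
exposure — here the summed anticholinergic burden (ACB) of a participant's
medication, an integer score with observed range 0–4 — is associated with
the *level* of a longitudinal outcome (a cognitive composite, a timed test,
a normalized regional brain volume) and with its *rate of change* over
time. Two features make this statistically awkward:

1. The data are hierarchical: repeated visits are nested within
   individuals, each of whom has their own baseline level and their own
   slope.
2. The scientific question is a *model comparison* — is there evidence for
   the burden terms at all? — and classical Bayes factors for mixed models
   are notoriously sensitive to the parameter priors.

This package implements the analysis built around these two constraints: a
Bayesian Gaussian linear mixed model with random intercepts and slopes,
compared across nested fixed-effect structures by a **cross-validated
Bayes factor (CVBF)** that replaces the marginal likelihood with a held-out
posterior predictive likelihood under repeated subject-level data splits.

## The model

For subject $i$ at visit time $t_{ij}$ (years since baseline),

$$y_{ij} = x_{ij}^\top \beta + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim \mathcal N_2(0, G)$,
$G = \begin{pmatrix} \tau_0^2 & \rho\tau_0\tau_1 \\ \rho\tau_0\tau_1 & \tau_1^2\end{pmatrix}$,
and $\varepsilon_{ij} \sim \mathcal N(0, \sigma^2)$ i.i.d.

The alternative model's fixed effects are: intercept, time, ACB score, ACB
× time, diagnostic group (CN reference; Rel, SCD, MCI, ADD dummies),
group × time, sex (male reference), age, and education, giving $p = 15$
columns for a five-level factor. The null model drops the burden term(s)
under test. An optional sensitivity refit adds ApoE e4 carrier status and
its time interaction. All outcomes are analysed as Gaussian; bounded
ordinal scales (CDR-like scores) are treated as continuous. This is a
deliberate simplification — the Gaussian family is what makes the held-out
random-effect marginalization below available in closed form — and is the
package's main distributional limitation.

### Priors and standardization

Fixed-effect priors are independent $\mathcal N(0, s)$ with a common SD:
$s = 1$ ("mildly informative"), $s = 0.5$ ("moderately informative"), or
$s = 10^4$ (a proper, numerically safe stand-in for a flat prior). A fixed
prior SD is only meaningful on a common scale, so by default the outcome
and the continuous covariates (age, education, ACB score) are z-scored on
the data used for fitting; time stays in years and dummy variables stay
0/1. The standardized design is an **exact linear transformation** of the
raw design (the centering of ACB in the ACB × time column flows into the
time column), and the transformation matrix is stored, so posterior draws
are mapped back to original units exactly rather than approximately.

Variance-component priors are not part of the comparison of interest and
are fixed at weakly informative defaults: half-normal(0, 2.5) on
$\tau_0, \tau_1, \sigma$ (standardized scale) and uniform on
$\rho \in (-1, 1)$. The CVBF is designed to be insensitive to these
choices, and the prior-stability checks in the test suite exercise that
claim empirically.

## Posterior computation

The sampler never represents the random effects: for each subject
$V_i = Z_i G Z_i^\top + \sigma^2 I$ (with $Z_i = [1, t_i]$) gives the
marginal likelihood of $y_i$ directly, and the Gaussian prior on $\beta$
is also integrated analytically. What remains is a 4-dimensional marginal
posterior over $(\tau_0, \tau_1, \rho, \sigma)$, explored by
coordinate-wise random-walk Metropolis on unconstrained scales
($\log\tau_0, \log\tau_1, \operatorname{atanh}\rho, \log\sigma$) with
Robbins–Monro step-size adaptation (target acceptance 0.44) during warmup
only; $\beta$ is then drawn from its exact Gaussian conditional at each
retained iteration. This collapsed scheme avoids the funnel geometry that
plagues samplers of hierarchical models when variance components are near
zero, which matters here because null-model fits on null data live exactly
in that regime. Per-subject linear algebra is done in C++
(RcppArmadillo) through Cholesky factorizations of the small $n_i \times
n_i$ covariances.

Convergence is monitored by split-chain $\widehat R$ on every parameter,
with a warning above 1.05. All randomness is derived from a master seed
through named substreams (chain, split, bootstrap), so every result in
the package is bit-reproducible.

Degenerate inputs are rejected before sampling: rank-deficient designs
(the offending columns are named), fewer than two subjects with two or
more visits, and more fixed-effect columns than rows. Rows with missing
outcome or covariates are dropped per row — never whole subjects unless no
rows remain — with the count recorded on the design.

## The cross-validated Bayes factor

A single split assigns whole subjects (never individual visits — leaving
one observation out would break the hierarchical structure) to a training
half and a validation half, stratified by diagnosis so every dummy-coded
level occurs on both sides. Both models are fitted to the same training
rows. For a held-out subject the random effects are unknown, so each
posterior draw evaluates the subject's **marginal** likelihood
$\mathcal N(y_i \mid X_i\beta, Z_i G Z_i^\top + \sigma^2 I)$ — this is
the predictive density a genuinely new individual warrants, rather than
one conditioned on re-estimated subject effects. The held-out posterior
predictive density averages these over draws by log-sum-exp (safe for
per-draw log likelihoods anywhere in $[-10^6, 10^6]$), and the split's
Bayes factor is the ratio of the alternative's to the null's predictive
density.

Design choices where the construction is genuinely open, fixed here once:

* **Train fraction** 0.5, the two-part split of the original CVBF
  construction; configurable.
* **Number of splits** $K = 10$ by default; the analyses in the test suite
  and the acceptance script use $K = 5$ with 250–300 warmup/sampling
  iterations per chain, sizes chosen so the full calibration experiments
  run comfortably on a single CPU while leaving the operating
  characteristics intact.
* **Aggregation**: Bayes factors are ratio-scaled, so the aggregate is the
  geometric mean of per-split BFs (arithmetic mean of log-BFs), with a
  percentile bootstrap (10^4 resamples of the $K$ split values) giving a
  95% interval for that mean. The interval quantifies between-split
  uncertainty.
* **Paired seeds**: split plans derive only from the master seed, never
  from the prior, so prior-sensitivity comparisons are paired. Fit seeds
  derive from a model's term signature, so structurally identical models
  share draws and the self-comparison BF is exactly 1.
* **Effect blocks**: the evidence tables report three nested comparisons —
  dropping the burden main effect only, the burden × time interaction
  only, or both jointly. The full alternative model is always the
  reference; which single block a published table intends can be
  ambiguous, so the pipeline runs all requested blocks explicitly.

Evidence categories partition $(0,\infty)$ at 0.33, 3, 10, 30 and 100,
with upper bounds inclusive for the lower category (BF = 3 is still
"weak"; BF = 0.33 still supports the null). The 0.33 bound is the literal
decimal, not $1/3$ — immaterial at reporting precision but fixed for
exactness.

## The synthetic cohort generator

Real memory-clinic data of this kind are not freely shareable, so the
generator is a first-class module that emulates the *structure* of such a
cohort: five diagnostic groups (CN : Rel : SCD : MCI : ADD in the ratio
177 : 63 : 294 : 105 : 64, scalable), per-group Gaussian age and education,
observed sex ratios, and integer ACB scores 0–4 drawn from truncated
geometric distributions calibrated exactly to per-group means (CN 0.2,
Rel 0.14, SCD 0.5, MCI 0.4, ADD 0.5) — a shape chosen because published
score distributions concentrate at zero. ApoE e4 carrier probabilities
are not published per group; the defaults (0.20, 0.30, 0.35, 0.45, 0.60
from CN to ADD) are field-typical values chosen once. Visits follow an
annual schedule with independent per-visit Bernoulli dropout after
baseline, with per-group rates (0.35–0.60) tuned to median follow-ups of
roughly four years in controls down to two in dementia. Baseline burden is
held constant over time, matching an analysis design that uses baseline
exposure only.

Outcomes are generated from exactly the mixed model above. The default
PACC5-like composite lives on a z-score-like scale (random-intercept SD
0.7, residual SD 0.35) with burden coefficients −0.0727 (main) and
−0.0012 (× time); the default TMT-B-like timed test lives in seconds
(random-intercept SD 25, residual SD 18) with burden coefficients 0.3928
and 0.8018. The group, age, education and ApoE coefficients are plausible
values chosen once to give realistic separation between diagnostic
stages; they are package defaults, not estimates.

What the generator does **not** emulate: time-varying medication and
burden, practice effects and floor/ceiling in cognitive tests, informative
(outcome-dependent) dropout, site and scanner effects in volumetric
outcomes, and non-Gaussian residuals. Passing calibration tests on these
cohorts therefore demonstrates correctness of the machinery and sane
operating characteristics under the stated generative law — not robustness
to those real-data complications.

## What the tests establish

The test suite ties every layer to an independent oracle: the closed-form
held-out marginal likelihood against brute-force Monte-Carlo integration
over random effects (10^5 samples, 0.01 log-unit tolerance); the sampler
against the exact conjugate posterior in the fixed-effects-only,
known-variance reduction; credible-interval coverage of the burden × time
coefficient across replicate cohorts (60 subjects, 4 visits); CVBF
calibration on null cohorts (aggregate BF below 3 in at least 80% of
replicates, replicate geometric mean near 1) and detection of a 0.5
SD/year burden × time signal, with mean log-CVBF monotone over the effect
grid {0, 0.25, 0.5}; and paired prior stability within a factor of two.
The calibration experiments use 20 replicate cohorts of 60 subjects with
$K = 5$ splits each — small enough to run routinely, large enough for the
stated proportions to be meaningful. One caveat found and documented
during development: the posterior median of a truly-zero random-effect SD
is only ~0.15σ at 200 subjects × 4 visits (that is what the information in
the data supports, not a sampler artifact); the near-zero concentration
property is therefore tested at 800 subjects × 5 visits, where the 0.1σ
bound genuinely holds.

## Known limitations

* Gaussian outcomes only; no generalized families, splines, or nonlinear
  time trends.
* Single shared prior SD across fixed effects; per-coefficient prior
  scales are not exposed, so the standardized/unstandardized equivalence
  is exact only under the flat prior.
* Complete-case handling per row; no multiple imputation.
* The bootstrap interval reflects between-split variability only, not
  MCMC noise within a split (kept small by the exact collapsed draws of
  $\beta$).
* Bridge-sampling marginal likelihoods and pointwise leave-one-out
  cross-validation are intentionally out of scope; the CVBF exists
  precisely because both are unreliable or ill-posed for these models.
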