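# cvbflmm

Cross-validated Bayes factors for Bayesian linear mixed models of
longitudinal cohort data.

## The problem

Memory-clinic cohorts spanning the Alzheimer's clinical spectrum —
cognitively normal controls (CN), relatives of dementia patients (Rel),
subjective cognitive decline (SCD), mild cognitive impairment (MCI) and
Alzheimer's dementia (ADD) — are used to ask whether baseline
anticholinergic medication burden (an integer sum score, range 0–4) is
associated with the level and the rate of change of cognitive and
volumetric outcomes. The natural model is a linear mixed model with a
random intercept and slope per subject,

```
y_ij = x_ij' β + b0_i + b1_i t_ij + ε_ij,   (b0, b1) ~ N2(0, G),   ε ~ N(0, σ²),
```

with fixed effects for time, burden, burden × time, diagnostic group and
group × time, sex, age and education. The scientific question — *is there
evidence for the burden terms at all?* — is a Bayesian model comparison,
and classical Bayes factors for mixed models are highly sensitive to the
parameter priors.

This package implements the **cross-validated Bayes factor (CVBF)**: the
data are split repeatedly *by individuals* (respecting the hierarchy)
into a training and a validation half, both the alternative and the null
model are fitted to the training half by MCMC, and the Bayes factor for
each split is the ratio of held-out posterior predictive densities on
the validation half, with each held-out subject's random effects
marginalized in closed form:

```
BF_k = p_alt(y_val | y_train) / p_null(y_val | y_train)
CVBF = exp( mean_k log BF_k ),  with a percentile-bootstrap 95% CI
```

CVBF values map onto the usual evidence bands: ≤ 0.33 supports the null,
(0.33, 3] is weak, > 3 moderate, > 10 strong, > 30 very strong, > 100
extreme evidence. Because the prior enters only through the training
posterior, the CVBF is far less prior-sensitive than marginal-likelihood
Bayes factors.

Because the cohort data this design targets are not freely shareable, the
package includes a first-class synthetic-cohort generator that emulates
the study structure (group sizes, covariate distributions, burden-score
distributions calibrated to published group means, annual visits with
dropout) and generates outcomes from exactly the model above, so every
stage is testable end to end with known truth.

## Worked example

```r
library(cvbflmm)

# quarter-scale synthetic cohort: 176 subjects, 576 visit rows
cohort <- generate_cohort(default_sim_config(scale = 0.25, seed = 42))

# evidence for the burden main effect on the PACC5-like composite
alt  <- model_spec("PACC5")
null <- drop_terms(alt, "acb")
cvbf(cohort, alt, null, prior_spec("normal_sd_0.5"), K = 5,
     mcmc = mcmc_control(chains = 1, warmup = 300, draws = 300),
     seed = 42, comparison = "main")
#> <cvbf_result> PACC5 (main, prior normal_sd_0.5)
#>   CV-BF = 1.15  [95% CI 0.278 - 6.89]  -> weak  (K = 5)

# full-data parameter estimates under the N(0, 0.5) prior
d  <- build_design(cohort, alt)
dr <- sample_posterior(d, prior_spec("normal_sd_0.5"),
                       mcmc_control(chains = 2, warmup = 400, draws = 400),
                       seed = 42)
s  <- summarize_posterior(dr, d)
s[s$term %in% c("acb", "acb:time"), ]
#>       term estimate ci_lower ci_upper excludes_zero
#> 3      acb -0.17057  -0.3059  -0.0265          TRUE
#> 4 acb:time  0.00877  -0.0272   0.0480         FALSE
```

Read: at this quarter scale the cross-validated evidence for the burden
main effect is weak (CV-BF 1.15, interval spanning 1), while the
parameter estimate for burden is negative with a 95% credible interval
excluding zero (−0.17 per burden point on the composite scale, i.e. lower
cognition with higher burden) and the burden × time interaction is
indistinguishable from zero. Estimates are reported in original outcome
units; fitting happens on a standardized scale where the N(0, 0.5) and
N(0, 1) priors are meaningful.

The full pipeline (simulate → fit → cvbf → report, with CSV tables and a
JSON manifest) runs from a YAML config:

```r
run_pipeline(system.file("extdata", "demo_run.yaml", package = "cvbflmm"))
```

or from a shell via `Rscript inst/cli/cvbf_lmm.R run --config <yaml>
[--seed N] [--out DIR]` (subcommands `simulate`, `fit`, `cvbf`, `report`
run the stages individually and compose to the identical bundle).

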