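# Configuration objects for the synthetic-cohort generator.

DIAGNOSIS_LEVELS <- c("CN", "Rel", "SCD", "MCI", "ADD")

#' Calibrate an integer burden-score distribution to a target mean
#'
#' Anticholinergic burden sum scores are small integers (observed range 0-4)
#' with most of the probability mass at zero. We use a truncated geometric
#' family `p(k) proportional to r^k`, `k = 0..max_score`, and solve for the
#' ratio `r` that matches the requested mean. This concentrates mass at zero
#' while hitting the published per-group means exactly.
#'
#' @param target_mean desired mean score, in `(0, max_score)`.
#' @param max_score largest attainable score (default 4).
#' @return probability vector over scores `0:max_score`, summing to one.
#' @export
#' @examples
#' p <- acb_probs_for_mean(0.5)
#' sum(p * 0:4) # 0.5
acb_probs_for_mean <- function(target_mean, max_score = 4L) {
  stopifnot(target_mean > 0, target_mean < max_score)
  k <- 0:max_score
  mean_at <- function(logr) {
    w <- exp(k * logr)
    sum(k * w) / sum(w)
  }
  logr <- uniroot(function(lr) mean_at(lr) - target_mean,
                  lower = -30, upper = 30, tol = 1e-12)$root
  w <- exp(k * logr)
  w / sum(w)
}

#' Specify the generative law of one longitudinal outcome
#'
#' Outcomes follow a linear mixed model: fixed effects on the raw covariate
#' scale plus a subject-specific random intercept and slope (bivariate
#' normal) plus i.i.d. Gaussian residual noise.
#'
#' @param name outcome column name.
#' @param beta named numeric vector of true fixed-effect coefficients. Names
#'   must match design columns: `"(Intercept)"`, `"time"`, `"acb"`,
#'   `"acb:time"`, `"diagnosisRel"`, ..., `"diagnosisADD:time"`,
#'   `"sexfemale"`, `"age"`, `"education"`, `"apoe4"`, `"apoe4:time"`.
#' @param tau_intercept,tau_slope random-effect standard deviations
#'   (outcome units; units per year).
#' @param re_correlation intercept-slope correlation in `[-1, 1]`.
#' @param sigma residual standard deviation.
#' @param missing_frac fraction of generated values blanked at random
#'   (default 0), to exercise missing-data handling downstream.
#' @return an object of class `outcome_gen_spec`.
#' @export
outcome_gen_spec <- function(name, beta, tau_intercept, tau_slope,
                             re_correlation = 0, sigma = 1,
                             missing_frac = 0) {
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop_config("outcome '%s': beta must be a fully named numeric vector", name)
  if (tau_intercept < 0) stop_config("outcome '%s': tau_intercept must be >= 0", name)
  if (tau_slope < 0) stop_config("outcome '%s': tau_slope must be >= 0", name)
  if (sigma < 0) stop_config("outcome '%s': sigma must be >= 0", name)
  if (abs(re_correlation) > 1)
    stop_config("outcome '%s': re_correlation must lie in [-1, 1]", name)
  if (missing_frac < 0 || missing_frac >= 1)
    stop_config("outcome '%s': missing_frac must lie in [0, 1)", name)
  structure(list(name = name, beta = beta, tau_intercept = tau_intercept,
                 tau_slope = tau_slope, re_correlation = re_correlation,
                 sigma = sigma, missing_frac = missing_frac),
            class = "outcome_gen_spec")
}

check_prob_vector <- function(p, field) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop_config("field '%s': probabilities must be non-negative and sum to 1", field)
  invisible(p)
}

#' Configure a synthetic longitudinal cohort
#'
#' Describes a memory-clinic style cohort spanning cognitively normal (CN)
#' participants, relatives of dementia patients (Rel), subjective cognitive
#' decline (SCD), mild cognitive impairment (MCI) and Alzheimer's dementia
#' (ADD), with per-group covariate distributions, an annual visit schedule
#' with dropout, and one or more model-generated outcomes.
#'
#' @param group_sizes named integer vector of subjects per diagnosis.
#' @param acb_distribution named list: per-group probability vector over
#'   integer burden scores 0..4.
#' @param age_mean_sd,education_mean_sd named lists of `c(mean, sd)` per group
#'   (years).
#' @param sex_female_prob,apoe4_prob named numeric vectors of per-group
#'   probabilities.
#' @param visit_times intended visit times in years, strictly increasing and
#'   starting at 0.
#' @param dropout_prob per-visit probability (scalar or per-group) that a
#'   post-baseline visit is missed; misses are independent across visits.
#' @param visit_jitter half-width in years of uniform jitter applied to
#'   post-baseline visit times (default 0 = exact schedule).
#' @param outcome_specs list of [outcome_gen_spec()] objects.
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(group_sizes, acb_distribution, age_mean_sd,
                       education_mean_sd, sex_female_prob, apoe4_prob,
                       visit_times = 0:4, dropout_prob = 0.5,
                       visit_jitter = 0, outcome_specs = list(),
                       seed = 1L) {
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% DIAGNOSIS_LEVELS))
    stop_config("field 'group_sizes': names must be among %s",
                paste(DIAGNOSIS_LEVELS, collapse = ", "))
  if (any(group_sizes < 1)) stop_config("field 'group_sizes': all sizes must be >= 1")
  if (visit_times[1] != 0 || any(diff(visit_times) <= 0))
    stop_config("field 'visit_times': must be strictly increasing and start at 0")
  for (g in groups) check_prob_vector(acb_distribution[[g]],
                                      paste0("acb_distribution$", g))
  for (g in groups) {
    if (age_mean_sd[[g]][2] < 0) stop_config("field 'age_mean_sd$%s': sd must be >= 0", g)
    if (education_mean_sd[[g]][2] < 0)
      stop_config("field 'education_mean_sd$%s': sd must be >= 0", g)
    if (sex_female_prob[[g]] < 0 || sex_female_prob[[g]] > 1)
      stop_config("field 'sex_female_prob$%s': must be a probability", g)
    if (apoe4_prob[[g]] < 0 || apoe4_prob[[g]] > 1)
      stop_config("field 'apoe4_prob$%s': must be a probability", g)
  }
  if (length(dropout_prob) == 1L)
    dropout_prob <- setNames(rep(dropout_prob, length(groups)), groups)
  if (any(dropout_prob < 0 | dropout_prob > 1))
    stop_config("field 'dropout_prob': must be probabilities")
  min_gap <- if (length(visit_times) > 1) min(diff(visit_times)) else Inf
  if (visit_jitter < 0 || visit_jitter >= min_gap / 2)
    stop_config("field 'visit_jitter': must be >= 0 and small enough to keep visit order")
  structure(list(group_sizes = group_sizes, acb_distribution = acb_distribution,
                 age_mean_sd = age_mean_sd, education_mean_sd = education_mean_sd,
                 sex_female_prob = sex_female_prob, apoe4_prob = apoe4_prob,
                 visit_times = visit_times, dropout_prob = dropout_prob,
                 visit_jitter = visit_jitter, outcome_specs = outcome_specs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default generative specification for a PACC5-like cognitive composite
#'
#' A global cognitive composite on a z-score-like scale (population SD near
#' 1), declining with disease stage, age and anticholinergic burden. The
#' burden coefficients default to a small negative cross-sectional effect
#' (-0.0727 per burden point) and an essentially null time interaction.
#'
#' @param acb_beta,acb_time_beta true burden main and time-interaction
#'   coefficients.
#' @param ... passed through to [outcome_gen_spec()] to override variance
#'   components.
#' @return an `outcome_gen_spec`.
#' @export
pacc5_gen_spec <- function(acb_beta = -0.0727, acb_time_beta = -0.0012, ...) {
  beta <- c(
    "(Intercept)" = 1.3, "time" = -0.05,
    "acb" = acb_beta, "acb:time" = acb_time_beta,
    "diagnosisRel" = 0.05, "diagnosisSCD" = -0.15,
    "diagnosisMCI" = -1.0, "diagnosisADD" = -2.2,
    "diagnosisRel:time" = 0, "diagnosisSCD:time" = -0.08,
    "diagnosisMCI:time" = -0.25, "diagnosisADD:time" = -0.45,
    "sexfemale" = 0.15, "age" = -0.03, "education" = 0.06,
    "apoe4" = -0.11, "apoe4:time" = -0.02)
  defaults <- list(name = "PACC5", beta = beta, tau_intercept = 0.7,
                   tau_slope = 0.15, re_correlation = -0.2, sigma = 0.35)
  do.call(outcome_gen_spec, utils::modifyList(defaults, list(...)))
}

#' Default generative specification for a TMT-B-like timed test
#'
#' Completion time in seconds (higher = worse), increasing with disease
#' stage and age. The burden coefficients default to a weak positive main
#' effect (0.3928 s per burden point) and a positive time interaction
#' (0.8018 s/year per burden point, i.e. faster worsening with burden).
#'
#' @inheritParams pacc5_gen_spec
#' @return an `outcome_gen_spec`.
#' @export
tmtb_gen_spec <- function(acb_beta = 0.3928, acb_time_beta = 0.8018, ...) {
  beta <- c(
    "(Intercept)" = 10, "time" = 2,
    "acb" = acb_beta, "acb:time" = acb_time_beta,
    "diagnosisRel" = 0, "diagnosisSCD" = 5,
    "diagnosisMCI" = 25, "diagnosisADD" = 60,
    "diagnosisRel:time" = 0, "diagnosisSCD:time" = 1,
    "diagnosisMCI:time" = 5, "diagnosisADD:time" = 12,
    "sexfemale" = 0, "age" = 1.0, "education" = -1.2,
    "apoe4" = 3, "apoe4:time" = 2.38)
  defaults <- list(name = "TMTB", beta = beta, tau_intercept = 25,
                   tau_slope = 6, re_correlation = 0.3, sigma = 18)
  do.call(outcome_gen_spec, utils::modifyList(defaults, list(...)))
}

#' Default cohort configuration
#'
#' Reproduces the structure of a memory-clinic cohort at a configurable
#' scale: five diagnostic groups with published per-group sample sizes in
#' the ratio 177:63:294:105:64, burden-score distributions calibrated to
#' per-group means (CN 0.2, Rel 0.14, SCD 0.5, MCI 0.4, ADD 0.5), per-group
#' age and education Gaussians, observed sex ratios, an annual five-visit
#' schedule and per-group dropout tuned to a median follow-up around three
#' years (longer in controls, shorter in dementia).
#'
#' @param scale multiplier on the full-cohort group sizes (default 0.25).
#' @param outcome_specs list of [outcome_gen_spec()]; defaults to a
#'   PACC5-like composite and a TMT-B-like timed test.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
default_sim_config <- function(scale = 0.25,
                               outcome_specs = list(pacc5_gen_spec(),
                                                    tmtb_gen_spec()),
                               seed = 1L, ...) {
  full <- c(CN = 177, Rel = 63, SCD = 294, MCI = 105, ADD = 64)
  sizes <- pmax(1L, as.integer(round(full * scale)))
  names(sizes) <- names(full)
  acb_means <- c(CN = 0.2, Rel = 0.14, SCD = 0.5, MCI = 0.4, ADD = 0.5)
  args <- list(
    group_sizes = sizes,
    acb_distribution = lapply(acb_means, acb_probs_for_mean),
    age_mean_sd = list(CN = c(69.2, 5.3), Rel = c(66.6, 4.7),
                       SCD = c(71.0, 6.1), MCI = c(73.0, 5.7),
                       ADD = c(74.8, 6.4)),
    education_mean_sd = list(CN = c(14.8, 2.8), Rel = c(14.8, 2.8),
                             SCD = c(14.9, 3.0), MCI = c(14.1, 3.1),
                             ADD = c(12.5, 3.1)),
    sex_female_prob = c(CN = 97 / 177, Rel = 35 / 63, SCD = 134 / 294,
                        MCI = 46 / 105, ADD = 35 / 64),
    apoe4_prob = c(CN = 0.20, Rel = 0.30, SCD = 0.35, MCI = 0.45, ADD = 0.60),
    visit_times = 0:4,
    dropout_prob = c(CN = 0.35, Rel = 0.50, SCD = 0.50, MCI = 0.50, ADD = 0.60),
    outcome_specs = outcome_specs,
    seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
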