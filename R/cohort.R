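# Cohort generation, validation and CSV round-trip.

#' Raw design basis for a cohort
#'
#' Builds the full set of raw-scale design columns used both by the outcome
#' generator and (after standardization) by the model fitter: intercept,
#' time, burden score, burden-by-time, diagnosis dummies against a reference
#' level with their time interactions, sex, age, education, and (when the
#' cohort carries them) ApoE e4 terms.
#'
#' @param cohort a cohort data frame.
#' @param reference_diagnosis reference level for dummy coding.
#' @param diag_levels diagnosis levels to code (default: levels present).
#' @return numeric matrix with named columns.
#' @keywords internal
raw_basis <- function(cohort, reference_diagnosis = "CN", diag_levels = NULL) {
  if (is.null(diag_levels)) {
    diag_levels <- DIAGNOSIS_LEVELS[DIAGNOSIS_LEVELS %in% unique(cohort$diagnosis)]
  }
  if (!reference_diagnosis %in% diag_levels)
    stop_config("reference diagnosis '%s' absent from cohort levels (%s)",
                reference_diagnosis, paste(diag_levels, collapse = ", "))
  n <- nrow(cohort)
  cols <- list("(Intercept)" = rep(1, n), time = cohort$time,
               acb = as.numeric(cohort$acb_score),
               "acb:time" = as.numeric(cohort$acb_score) * cohort$time)
  for (lv in setdiff(diag_levels, reference_diagnosis)) {
    d <- as.numeric(cohort$diagnosis == lv)
    cols[[paste0("diagnosis", lv)]] <- d
    cols[[paste0("diagnosis", lv, ":time")]] <- d * cohort$time
  }
  cols$sexfemale <- as.numeric(cohort$sex == "female")
  cols$age <- cohort$age
  cols$education <- cohort$education
  if ("apoe4" %in% names(cohort) && !all(is.na(cohort$apoe4))) {
    cols$apoe4 <- as.numeric(cohort$apoe4)
    cols[["apoe4:time"]] <- as.numeric(cohort$apoe4) * cohort$time
  }
  do.call(cbind, cols)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject baseline covariates from the configured per-group
#' distributions, applies the visit schedule with independent per-visit
#' dropout (baseline always retained), and simulates every configured
#' outcome under its linear mixed model. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a long-format cohort `data.frame` (class `cohort_table`), one row
#'   per subject-visit, ordered by subject then time.
#' @export
#' @examples
#' cfg <- default_sim_config(scale = 0.05, seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "covariates"))
  groups <- names(config$group_sizes)
  subj <- do.call(rbind, lapply(groups, function(g) {
    n <- config$group_sizes[[g]]
    data.frame(
      subject_id = sprintf("%s-%04d", g, seq_len(n)),
      diagnosis = g,
      sex = ifelse(rbinom(n, 1, config$sex_female_prob[[g]]) == 1,
                   "female", "male"),
      age = rnorm(n, config$age_mean_sd[[g]][1], config$age_mean_sd[[g]][2]),
      education = rnorm(n, config$education_mean_sd[[g]][1],
                        config$education_mean_sd[[g]][2]),
      apoe4 = rbinom(n, 1, config$apoe4_prob[[g]]),
      acb_score = sample(0:4, n, replace = TRUE,
                         prob = config$acb_distribution[[g]]),
      stringsAsFactors = FALSE)
  }))

  set.seed(substream_seed(config$seed, "visits"))
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    g <- subj$diagnosis[i]
    later <- config$visit_times[-1]
    keep <- runif(length(later)) >= config$dropout_prob[[g]]
    times <- c(0, later[keep])
    if (config$visit_jitter > 0 && length(times) > 1) {
      times[-1] <- times[-1] +
        runif(length(times) - 1, -config$visit_jitter, config$visit_jitter)
    }
    cbind(subj[rep(i, length(times)), , drop = FALSE],
          data.frame(time = times))
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort <- cohort[order(cohort$subject_id, cohort$time), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")

  for (k in seq_along(config$outcome_specs)) {
    spec <- config$outcome_specs[[k]]
    cohort <- simulate_outcomes(
      cohort, spec, seed = substream_seed(config$seed, "outcome", k))
  }
  validate_cohort(cohort)
  cohort
}

#' Simulate one outcome column under the random-intercept-and-slope model
#'
#' Adds a column `spec$name` with values
#' `y_ij = x_ij' beta + b0_i + b1_i t_ij + e_ij`, where `(b0, b1)` is
#' bivariate normal with standard deviations `tau_intercept`, `tau_slope`
#' and correlation `re_correlation`, and `e_ij` is i.i.d. normal with
#' standard deviation `sigma`.
#'
#' @param cohort a cohort data frame.
#' @param spec an [outcome_gen_spec()].
#' @param seed integer seed; generation is deterministic given it.
#' @return the cohort with the outcome column added (existing column of the
#'   same name is overwritten).
#' @export
simulate_outcomes <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(spec, "outcome_gen_spec"))
  # code all five diagnosis levels so absent groups contribute zero columns
  basis <- raw_basis(cohort, "CN", DIAGNOSIS_LEVELS)
  missing_terms <- setdiff(names(spec$beta), colnames(basis))
  if (length(missing_terms) > 0)
    stop_config("outcome '%s': unresolvable term(s): %s", spec$name,
                paste(missing_terms, collapse = ", "))
  X <- basis[, names(spec$beta), drop = FALSE]
  mu <- as.vector(X %*% spec$beta)

  set.seed(seed)
  ids <- unique(cohort$subject_id)
  nsub <- length(ids)
  # bivariate normal random effects via Cholesky of the 2x2 covariance
  z <- matrix(rnorm(2 * nsub), nsub, 2)
  t0 <- spec$tau_intercept; t1 <- spec$tau_slope; rho <- spec$re_correlation
  b0 <- t0 * z[, 1]
  b1 <- t1 * (rho * z[, 1] + sqrt(max(0, 1 - rho^2)) * z[, 2])
  idx <- match(cohort$subject_id, ids)
  y <- mu + b0[idx] + b1[idx] * cohort$time +
    rnorm(nrow(cohort), 0, spec$sigma)
  if (spec$missing_frac > 0) {
    y[runif(length(y)) < spec$missing_frac] <- NA_real_
  }
  cohort[[spec$name]] <- y
  cohort
}

#' Validate cohort invariants
#'
#' Checks the structural contract of a long-format cohort: required columns,
#' integer burden scores in 0..4, non-negative times unique within subject,
#' a baseline (time 0) row for every subject, and baseline covariates
#' constant within subject. Errors enumerate the offending rows or subjects.
#'
#' @param cohort a data frame.
#' @return the cohort, invisibly, with class `cohort_table`.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject_id", "diagnosis", "sex", "age", "education",
                "acb_score", "time")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0)
    stop_config("cohort is missing required column(s): %s",
                paste(miss, collapse = ", "))
  bad_diag <- which(!cohort$diagnosis %in% DIAGNOSIS_LEVELS)
  if (length(bad_diag) > 0)
    stop_config("column 'diagnosis': invalid level(s) at row(s) %s",
                paste(utils::head(bad_diag, 10), collapse = ", "))
  bad_acb <- which(is.na(cohort$acb_score) |
                     cohort$acb_score != round(cohort$acb_score) |
                     cohort$acb_score < 0 | cohort$acb_score > 4)
  if (length(bad_acb) > 0)
    stop_config("column 'acb_score': non-integer or out-of-range value(s) at row(s) %s",
                paste(utils::head(bad_acb, 10), collapse = ", "))
  bad_time <- which(is.na(cohort$time) | cohort$time < 0)
  if (length(bad_time) > 0)
    stop_config("column 'time': negative or missing value(s) at row(s) %s",
                paste(utils::head(bad_time, 10), collapse = ", "))
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  no_baseline <- names(sp)[vapply(sp, function(r) min(cohort$time[r]) != 0,
                                  logical(1))]
  if (length(no_baseline) > 0)
    stop_config("subject(s) without a time-0 baseline row: %s",
                paste(utils::head(no_baseline, 10), collapse = ", "))
  dup <- names(sp)[vapply(sp, function(r) anyDuplicated(cohort$time[r]) > 0,
                          logical(1))]
  if (length(dup) > 0)
    stop_config("duplicate (subject, time) pairs for subject(s): %s",
                paste(utils::head(dup, 10), collapse = ", "))
  baseline_cols <- intersect(c("diagnosis", "sex", "age", "education",
                               "apoe4", "acb_score"), names(cohort))
  varying <- names(sp)[vapply(sp, function(r) {
    any(vapply(baseline_cols, function(cl) {
      v <- cohort[[cl]][r]
      length(unique(v[!is.na(v)])) > 1
    }, logical(1)))
  }, logical(1))]
  if (length(varying) > 0)
    stop_config("baseline covariates vary within subject(s): %s",
                paste(utils::head(varying, 10), collapse = ", "))
  if (!inherits(cohort, "cohort_table"))
    class(cohort) <- c("cohort_table", class(cohort))
  invisible(cohort)
}

outcome_columns <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "diagnosis", "sex", "age",
                           "education", "apoe4", "acb_score", "time"))
}

#' Write / read a cohort as CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' save-then-load round trip reproduces every value bit-exactly. Empty cells
#' denote missing values. [load_cohort()] validates the result and reports
#' offending rows.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `save_cohort`: the path, invisibly. `load_cohort`: a validated
#'   `cohort_table`.
#' @export
save_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- ""
      out[[cl]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("subject_id", "diagnosis", "sex", "age", "education",
                "acb_score", "time")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0)
    stop_config("file '%s' is missing required column(s): %s", path,
                paste(miss, collapse = ", "))
  for (cl in setdiff(names(raw), c("subject_id", "diagnosis", "sex"))) {
    raw[[cl]] <- as.numeric(raw[[cl]])
  }
  validate_cohort(raw)
}
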