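# Model and prior specification, design construction, standardization.

FIXED_TERM_SET <- c("intercept", "time", "acb", "acb_time", "diagnosis",
                    "diagnosis_time", "sex", "age", "education", "apoe4",
                    "apoe4_time")

#' Specify a linear mixed model for one outcome
#'
#' Fixed-effect terms are drawn from a closed vocabulary covering the
#' covariates of the cohort analysis: time since baseline, anticholinergic
#' burden (main effect and time interaction), diagnostic group dummies with
#' their time interactions, sex, age, education, and optional ApoE e4 terms.
#' Random effects are always a per-subject intercept and slope on time.
#'
#' @param outcome outcome column name.
#' @param fixed_terms character vector of term labels (see Details). The
#'   intercept is always included; `diagnosis_time` requires `diagnosis`,
#'   and any interaction with time requires `time`.
#' @param reference_diagnosis reference level for dummy coding (default CN).
#' @param standardize standardize the outcome and the continuous covariates
#'   (age, education, burden score) to the training sample (default TRUE);
#'   fixed-effect priors are interpreted on this standardized scale.
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' alt <- model_spec("PACC5", c("time", "acb", "acb_time", "diagnosis",
#'                              "diagnosis_time", "sex", "age", "education"))
#' null <- drop_terms(alt, c("acb", "acb_time"))
model_spec <- function(outcome,
                       fixed_terms = c("time", "acb", "acb_time", "diagnosis",
                                       "diagnosis_time", "sex", "age",
                                       "education"),
                       reference_diagnosis = "CN", standardize = TRUE) {
  fixed_terms <- setdiff(unique(fixed_terms), "intercept")
  unknown <- setdiff(fixed_terms, FIXED_TERM_SET)
  if (length(unknown) > 0)
    stop_config("unknown fixed term(s): %s", paste(unknown, collapse = ", "))
  if ("diagnosis_time" %in% fixed_terms && !"diagnosis" %in% fixed_terms)
    stop_config("term 'diagnosis_time' requires 'diagnosis'")
  needs_time <- c("acb_time", "diagnosis_time", "apoe4_time")
  if (any(needs_time %in% fixed_terms) && !"time" %in% fixed_terms)
    stop_config("interaction terms with time require the 'time' main effect")
  structure(list(outcome = outcome,
                 fixed_terms = c("intercept", fixed_terms),
                 random_terms = c("intercept", "time"),
                 reference_diagnosis = reference_diagnosis,
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

#' Drop fixed-effect terms from a model specification
#'
#' Convenience for building nested null models, e.g. removing both burden
#' terms to form the null of the joint comparison.
#'
#' @param spec a [model_spec()].
#' @param terms term labels to remove.
#' @return a new `model_spec`.
#' @export
drop_terms <- function(spec, terms) {
  stopifnot(inherits(spec, "model_spec"))
  model_spec(spec$outcome,
             fixed_terms = setdiff(spec$fixed_terms, c("intercept", terms)),
             reference_diagnosis = spec$reference_diagnosis,
             standardize = spec$standardize)
}

#' Prior specification for the fixed effects
#'
#' Three options mirror a typical sensitivity design: a mildly informative
#' N(0, 1) prior, a moderately informative N(0, 0.5) prior, and an
#' effectively flat prior (normal with SD 1e4, a proper and numerically
#' safe stand-in for an improper flat prior). The SD applies to every
#' fixed-effect coefficient on the standardized scale. Variance components
#' always get half-normal(0, 2.5) priors on the standard deviations and a
#' uniform prior on the intercept-slope correlation.
#'
#' @param kind one of `"normal_sd_1"`, `"normal_sd_0.5"`, `"flat"`.
#' @return an object of class `prior_spec` with element `beta_sd`.
#' @export
prior_spec <- function(kind = c("normal_sd_0.5", "normal_sd_1", "flat")) {
  kind <- match.arg(kind)
  beta_sd <- switch(kind, normal_sd_1 = 1, normal_sd_0.5 = 0.5, flat = 1e4)
  structure(list(kind = kind, beta_sd = beta_sd, tau_scale = 2.5),
            class = "prior_spec")
}

# expand term labels into raw design column names
expand_terms <- function(fixed_terms, diag_levels, reference) {
  dummies <- paste0("diagnosis", setdiff(diag_levels, reference))
  out <- character(0)
  for (tm in fixed_terms) {
    out <- c(out, switch(tm,
      intercept = "(Intercept)", time = "time", acb = "acb",
      acb_time = "acb:time",
      diagnosis = dummies,
      diagnosis_time = paste0(dummies, ":time"),
      sex = "sexfemale", age = "age", education = "education",
      apoe4 = "apoe4", apoe4_time = "apoe4:time"))
  }
  out
}

# cohort columns a term set depends on (for complete-case filtering)
term_dependencies <- function(fixed_terms) {
  dep <- c(time = "time", acb = "acb_score", acb_time = "acb_score",
           diagnosis = "diagnosis", diagnosis_time = "diagnosis",
           sex = "sex", age = "age", education = "education",
           apoe4 = "apoe4", apoe4_time = "apoe4")
  unique(c("time", unname(dep[intersect(fixed_terms, names(dep))])))
}

#' Build per-subject design matrices for a mixed-model fit
#'
#' Assembles the fixed-effect design, random-effect times and response,
#' grouped and ordered by subject then time. Continuous covariates (age,
#' education, burden score) and the outcome are z-scored on the data at
#' hand when `spec$standardize` is set; passing the `stats` of a training
#' design instead applies the training offsets and scales, as required when
#' evaluating held-out subjects. Rows with missing outcome or covariates
#' are dropped (count retained in the result).
#'
#' The standardized design is an exact linear transformation of the raw
#' design; the transformation matrix is stored so that posterior draws can
#' be mapped back to the original outcome and covariate units.
#'
#' @param cohort a cohort data frame.
#' @param spec a [model_spec()].
#' @param stats optional standardization/coding statistics from a previous
#'   (training) call, taken from `design$stats`.
#' @return an object of class `lmm_design`.
#' @export
build_design <- function(cohort, spec, stats = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$outcome %in% names(cohort))
    stop_config("unknown outcome column '%s'", spec$outcome)
  needed <- term_dependencies(spec$fixed_terms)
  use_cols <- c(spec$outcome, needed)
  keep <- stats::complete.cases(cohort[, use_cols, drop = FALSE])
  dropped <- sum(!keep)
  dat <- cohort[keep, , drop = FALSE]
  dat <- dat[order(dat$subject_id, dat$time), , drop = FALSE]
  if (nrow(dat) == 0) stop_config("no complete rows for outcome '%s'", spec$outcome)

  if (is.null(stats)) {
    diag_levels <- DIAGNOSIS_LEVELS[DIAGNOSIS_LEVELS %in% unique(dat$diagnosis)]
    if (!spec$reference_diagnosis %in% diag_levels)
      stop_config("reference diagnosis '%s' absent from the data",
                  spec$reference_diagnosis)
    std <- list()
    if (spec$standardize) {
      y <- dat[[spec$outcome]]
      std$outcome <- c(center = mean(y), scale = sd_safe(y))
      for (v in intersect(c("age", "education"), needed)) {
        std[[v]] <- c(center = mean(dat[[v]]), scale = sd_safe(dat[[v]]))
      }
      if ("acb_score" %in% needed) {
        std$acb <- c(center = mean(dat$acb_score), scale = sd_safe(dat$acb_score))
      }
    }
    stats <- list(diag_levels = diag_levels,
                  reference = spec$reference_diagnosis,
                  standardize = spec$standardize, std = std)
  } else {
    unseen <- setdiff(unique(dat$diagnosis), stats$diag_levels)
    if (length(unseen) > 0)
      stop_config("diagnosis level(s) %s absent from the training coding",
                  paste(unseen, collapse = ", "))
  }

  basis <- raw_basis(dat, stats$reference, stats$diag_levels)
  cols <- expand_terms(spec$fixed_terms, stats$diag_levels, stats$reference)
  missing_cols <- setdiff(cols, colnames(basis))
  if (length(missing_cols) > 0)
    stop_config("cohort lacks data for design column(s): %s",
                paste(missing_cols, collapse = ", "))
  Xraw <- basis[, cols, drop = FALSE]

  p <- length(cols)
  Tm <- diag(p)
  dimnames(Tm) <- list(cols, cols)
  y <- dat[[spec$outcome]]
  y_center <- 0; y_scale <- 1
  if (stats$standardize) {
    y_center <- stats$std$outcome["center"]; y_scale <- stats$std$outcome["scale"]
    y <- (y - y_center) / y_scale
    for (v in c("age", "education")) {
      if (v %in% cols && !is.null(stats$std[[v]])) {
        cs <- stats$std[[v]]
        Tm[v, v] <- 1 / cs["scale"]
        Tm["(Intercept)", v] <- -cs["center"] / cs["scale"]
      }
    }
    if ("acb" %in% cols && !is.null(stats$std$acb)) {
      cs <- stats$std$acb
      Tm["acb", "acb"] <- 1 / cs["scale"]
      Tm["(Intercept)", "acb"] <- -cs["center"] / cs["scale"]
    }
    if ("acb:time" %in% cols && !is.null(stats$std$acb)) {
      cs <- stats$std$acb
      Tm["acb:time", "acb:time"] <- 1 / cs["scale"]
      Tm["time", "acb:time"] <- -cs["center"] / cs["scale"]
    }
  }
  X <- Xraw %*% Tm

  ids <- unique(dat$subject_id)
  idx <- match(dat$subject_id, ids)
  starts <- match(seq_along(ids), idx)
  ends <- length(idx) - match(seq_along(ids), rev(idx)) + 1L
  structure(list(y = as.numeric(y), X = X, col_names = cols,
                 times = dat$time, subject_ids = ids,
                 starts = as.integer(starts), ends = as.integer(ends),
                 transform = Tm,
                 y_center = unname(y_center), y_scale = unname(y_scale),
                 stats = stats, spec = spec, dropped_rows = dropped,
                 n_rows = nrow(dat), n_subjects = length(ids)),
            class = "lmm_design")
}

sd_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) 1 else s
}

#' @export
print.lmm_design <- function(x, ...) {
  cat(sprintf("<lmm_design> outcome '%s': %d rows, %d subjects, %d fixed columns",
              x$spec$outcome, x$n_rows, x$n_subjects, length(x$col_names)),
      if (x$dropped_rows > 0) sprintf(" (%d incomplete rows dropped)", x$dropped_rows),
      "\n", sep = "")
  invisible(x)
}
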