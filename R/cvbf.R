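# Cross-validated Bayes factors: subject-level splits, per-split held-out
# posterior predictive likelihood ratios, and aggregation across splits.

#' Split a cohort by individuals
#'
#' Assigns whole subjects (all their visits together) to a training or a
#' validation set, optionally stratified by diagnosis so that every
#' dummy-coded level appears in both halves. Deterministic under a seed.
#'
#' @param cohort a cohort data frame.
#' @param train_fraction fraction of subjects assigned to training,
#'   strictly between 0 and 1 (default 0.5).
#' @param stratify_by_diagnosis stratify the split on diagnosis
#'   (default TRUE).
#' @param seed integer seed.
#' @param split_id identifier stored in the plan.
#' @return an object of class `split_plan` with `train_ids` and
#'   `validation_ids`.
#' @export
split_by_individuals <- function(cohort, train_fraction = 0.5,
                                 stratify_by_diagnosis = TRUE, seed = 1L,
                                 split_id = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  subj <- unique(cohort[, c("subject_id", "diagnosis")])
  if (nrow(subj) < 4) stop_config("need at least 4 subjects to split")
  set.seed(seed)
  if (stratify_by_diagnosis) {
    groups <- split(subj$subject_id, subj$diagnosis)
    small <- names(groups)[vapply(groups, length, integer(1)) < 2]
    if (length(small) > 0)
      stop_config(paste0("diagnosis group(s) %s have fewer than 2 subjects; ",
                         "use stratify_by_diagnosis = FALSE"),
                  paste(small, collapse = ", "))
    train <- unlist(lapply(groups, function(ids) {
      k <- min(max(round(train_fraction * length(ids)), 1L), length(ids) - 1L)
      sample(ids, k)
    }), use.names = FALSE)
  } else {
    k <- min(max(round(train_fraction * nrow(subj)), 1L), nrow(subj) - 1L)
    train <- sample(subj$subject_id, k)
  }
  structure(list(split_id = split_id, train_ids = sort(train),
                 validation_ids = sort(setdiff(subj$subject_id, train)),
                 stratify_by = if (stratify_by_diagnosis) "diagnosis" else "none",
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

#' Log Bayes factor from a single train/validation split
#'
#' Fits the alternative and the null model to the training subjects and
#' returns the difference in held-out posterior predictive log density on
#' the validation subjects (random effects of held-out subjects
#' marginalized in closed form). Both models are fitted to the identical
#' training rows; validation designs use the training standardization.
#'
#' @param cohort a cohort data frame.
#' @param alt,null nested [model_spec()] objects (the null's terms must be
#'   a subset of the alternative's).
#' @param prior a [prior_spec()].
#' @param plan a [split_by_individuals()] plan.
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed for the two model fits.
#' @return a list with `log_bf` (natural log), `lpp_alt`, `lpp_null`, the
#'   plan, and per-model diagnostics.
#' @export
cvbf_single_split <- function(cohort, alt, null, prior = prior_spec(),
                              plan, mcmc = mcmc_control(), seed = 1L) {
  stopifnot(inherits(alt, "model_spec"), inherits(null, "model_spec"))
  if (!all(null$fixed_terms %in% alt$fixed_terms))
    stop_config("null model terms must be nested within the alternative")
  train <- cohort[cohort$subject_id %in% plan$train_ids, , drop = FALSE]
  valid <- cohort[cohort$subject_id %in% plan$validation_ids, , drop = FALSE]

  fit_one <- function(spec, label, fit_seed) {
    tr_design <- tryCatch(build_design(train, spec),
                          error = function(e)
                            stop_config("[%s model] %s", label, conditionMessage(e)))
    draws <- tryCatch(
      sample_posterior(tr_design, prior, mcmc, seed = fit_seed),
      error = function(e) stop_config("[%s model] %s", label, conditionMessage(e)))
    va_design <- tryCatch(build_design(valid, spec, stats = tr_design$stats),
                          error = function(e)
                            stop_config("[%s model] %s", label, conditionMessage(e)))
    list(lpp = log_posterior_predictive(draws, va_design),
         rhat = max(draws$diagnostics$rhat, na.rm = TRUE))
  }
  # fit seeds derive from the model's term signature, so structurally
  # identical specs share their draws (making BF = 1 exact in that case)
  model_seed <- function(spec)
    substream_seed(seed, paste0("model:", paste(spec$fixed_terms, collapse = "+")))
  fa <- fit_one(alt, "alternative", model_seed(alt))
  f0 <- fit_one(null, "null", model_seed(null))
  list(log_bf = fa$lpp - f0$lpp, lpp_alt = fa$lpp, lpp_null = f0$lpp,
       plan = plan, rhat_alt = fa$rhat, rhat_null = f0$rhat)
}

#' Cross-validated Bayes factor over repeated splits
#'
#' Runs [cvbf_single_split()] over `K` independently seeded subject-level
#' splits, aggregates by the geometric mean of the per-split Bayes factors
#' (arithmetic mean of log Bayes factors), and attaches a percentile
#' bootstrap 95% interval of that mean together with the verbal evidence
#' category of the aggregate.
#'
#' @inheritParams cvbf_single_split
#' @param K number of splits (>= 2, default 10).
#' @param train_fraction passed to [split_by_individuals()].
#' @param stratify_by_diagnosis passed to [split_by_individuals()].
#' @param seed master seed; split, fit and bootstrap seeds are derived
#'   substreams, so two calls with the same seed are identical and two
#'   priors evaluated with the same seed share their split plans.
#' @param n_boot bootstrap resamples for the interval (default 10000).
#' @param comparison label describing the term set under test.
#' @return an object of class `cvbf_result`.
#' @export
cvbf <- function(cohort, alt, null, prior = prior_spec(), K = 10L,
                 train_fraction = 0.5, stratify_by_diagnosis = TRUE,
                 mcmc = mcmc_control(), seed = 1L, n_boot = 10000L,
                 comparison = "main+interaction") {
  stopifnot(K >= 2)
  log_bfs <- rep(NA_real_, K)
  split_rows <- vector("list", K)
  failures <- character(0)
  for (k in seq_len(K)) {
    res <- tryCatch({
      plan <- split_by_individuals(cohort, train_fraction,
                                   stratify_by_diagnosis,
                                   seed = substream_seed(seed, "split", k),
                                   split_id = k)
      cvbf_single_split(cohort, alt, null, prior, plan, mcmc,
                        seed = substream_seed(seed, "fit", k))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("split %d: %s", k, conditionMessage(res)))
    } else {
      log_bfs[k] <- res$log_bf
      split_rows[[k]] <- data.frame(split_id = k, log_bf = res$log_bf,
                                    lpp_alt = res$lpp_alt,
                                    lpp_null = res$lpp_null,
                                    rhat_alt = res$rhat_alt,
                                    rhat_null = res$rhat_null)
    }
  }
  ok <- !is.na(log_bfs)
  if (sum(ok) < 2)
    stop_config("fewer than 2 splits succeeded (%d/%d): %s", sum(ok), K,
                paste(failures, collapse = "; "))
  lb <- log_bfs[ok]
  mean_log <- mean(lb)
  set.seed(substream_seed(seed, "bootstrap"))
  boot_means <- vapply(seq_len(n_boot), function(b)
    mean(lb[sample.int(length(lb), replace = TRUE)]), numeric(1))
  ci <- quantile(boot_means, c(0.025, 0.975), names = FALSE)
  structure(list(outcome = alt$outcome, comparison = comparison,
                 prior = prior$kind, log_bf_splits = log_bfs,
                 bf = exp(mean_log), ci_lower = exp(ci[1]),
                 ci_upper = exp(ci[2]),
                 category = as.character(categorize_bf(exp(mean_log))),
                 K = K, n_success = sum(ok), partial = any(!ok),
                 failures = failures, train_fraction = train_fraction,
                 splits = do.call(rbind, split_rows), seed = seed),
            class = "cvbf_result")
}

#' @export
print.cvbf_result <- function(x, ...) {
  cat(sprintf("<cvbf_result> %s (%s, prior %s)\n", x$outcome, x$comparison,
              x$prior))
  cat(sprintf("  CV-BF = %.3g  [95%% CI %.3g - %.3g]  -> %s  (K = %d%s)\n",
              x$bf, x$ci_lower, x$ci_upper, x$category, x$K,
              if (x$partial) sprintf(", %d splits failed", x$K - x$n_success)
              else ""))
  invisible(x)
}

#' Prior sensitivity analysis of the cross-validated Bayes factor
#'
#' Evaluates the same model comparison under several fixed-effect priors on
#' identical split plans (the split seeds derive only from the master
#' seed), enabling a paired comparison, and reports the largest pairwise
#' ratio of aggregate Bayes factors.
#'
#' @inheritParams cvbf
#' @param priors list of [prior_spec()] objects (>= 2).
#' @return an object of class `prior_sensitivity` with one [cvbf()] result
#'   per prior, a summary table, and `max_ratio`.
#' @export
prior_sensitivity <- function(cohort, alt, null, priors, K = 10L,
                              train_fraction = 0.5,
                              stratify_by_diagnosis = TRUE,
                              mcmc = mcmc_control(), seed = 1L,
                              comparison = "main+interaction") {
  stopifnot(length(priors) >= 2)
  results <- lapply(priors, function(pr)
    cvbf(cohort, alt, null, pr, K, train_fraction, stratify_by_diagnosis,
         mcmc, seed = seed, comparison = comparison))
  names(results) <- vapply(priors, function(pr) pr$kind, character(1))
  bfs <- vapply(results, function(r) r$bf, numeric(1))
  max_ratio <- max(outer(bfs, bfs, `/`))
  tab <- data.frame(prior = names(results), bf = unname(bfs),
                    ci_lower = vapply(results, function(r) r$ci_lower, numeric(1)),
                    ci_upper = vapply(results, function(r) r$ci_upper, numeric(1)),
                    category = vapply(results, function(r) r$category, character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, table = tab, max_ratio = max_ratio),
            class = "prior_sensitivity")
}

#' @export
print.prior_sensitivity <- function(x, ...) {
  cat("<prior_sensitivity>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  max pairwise BF ratio: %.3g\n", x$max_ratio))
  invisible(x)
}

#' Nested model comparisons for the burden effect
#'
#' Builds the (alternative, null) model pairs examined in the analysis:
#' `joint` drops both burden terms from the alternative, `main` drops only
#' the burden main effect, `interaction` drops only the burden-by-time
#' interaction.
#'
#' @param alt the full alternative [model_spec()] (must contain `acb` and
#'   `acb_time`).
#' @param blocks which comparisons to build.
#' @return named list of `list(alt = , null = )` pairs.
#' @export
comparison_blocks <- function(alt, blocks = c("main", "interaction", "joint")) {
  stopifnot(all(c("acb", "acb_time") %in% alt$fixed_terms))
  blocks <- match.arg(blocks, several.ok = TRUE)
  out <- list()
  if ("main" %in% blocks)
    out$main <- list(alt = alt, null = drop_terms(alt, "acb"))
  if ("interaction" %in% blocks)
    out$interaction <- list(alt = alt, null = drop_terms(alt, "acb_time"))
  if ("joint" %in% blocks)
    out$joint <- list(alt = alt, null = drop_terms(alt, c("acb", "acb_time")))
  out
}
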