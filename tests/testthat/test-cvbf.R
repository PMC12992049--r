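# CVBF engine: splits, identities, aggregation, prior sensitivity.

test_that("splits partition subjects and honour stratification", {
  co <- small_cohort(n_per_group = 10, seed = 1)
  plan <- split_by_individuals(co, 0.5, TRUE, seed = 3)
  ids <- unique(co$subject_id)
  expect_length(intersect(plan$train_ids, plan$validation_ids), 0)
  expect_setequal(c(plan$train_ids, plan$validation_ids), ids)
  # stratified: round(0.5 * 10) = 5 training subjects per diagnosis
  subj <- unique(co[, c("subject_id", "diagnosis")])
  tr_counts <- table(subj$diagnosis[subj$subject_id %in% plan$train_ids])
  expect_true(all(tr_counts == 5))

  p2 <- split_by_individuals(co, 0.5, TRUE, seed = 3)
  expect_identical(plan$train_ids, p2$train_ids)
  p3 <- split_by_individuals(co, 0.5, TRUE, seed = 4)
  expect_false(identical(plan$train_ids, p3$train_ids))
})

test_that("unstratifiable groups produce an actionable error", {
  co <- small_cohort(n_per_group = 4, seed = 2)
  solo <- co[co$diagnosis != "ADD" | co$subject_id == co$subject_id[1], ]
  expect_error(split_by_individuals(solo, 0.5, TRUE, seed = 1),
               "stratify_by_diagnosis = FALSE")
  expect_silent(split_by_individuals(solo, 0.5, FALSE, seed = 1))
})

test_that("a model compared against itself gives BF = 1 exactly", {
  co <- small_cohort(n_per_group = 5, seed = 3)
  alt <- model_spec("PACC5", c("time", "acb", "acb_time", "diagnosis",
                               "diagnosis_time"))
  mc <- mcmc_control(chains = 1, warmup = 100, draws = 80)
  plan <- split_by_individuals(co, 0.5, TRUE, seed = 5)
  r <- suppressWarnings(
    cvbf_single_split(co, alt, alt, prior_spec(), plan, mc, seed = 6))
  expect_identical(r$log_bf, 0)
  agg <- suppressWarnings(
    cvbf(co, alt, alt, prior_spec(), K = 3, mcmc = mc, seed = 7,
         comparison = "identity"))
  expect_identical(agg$bf, 1)
  expect_identical(agg$ci_lower, 1)
  expect_identical(agg$ci_upper, 1)
})

test_that("swapping the models negates the per-split log Bayes factor", {
  co <- small_cohort(n_per_group = 5, seed = 4, acb_time_beta = 0.3)
  alt <- model_spec("PACC5")
  null <- drop_terms(alt, c("acb", "acb_time"))
  mc <- mcmc_control(chains = 1, warmup = 100, draws = 80)
  plan <- split_by_individuals(co, 0.5, TRUE, seed = 8)
  # shared draws: fit each model once, evaluate both orderings by hand
  train <- co[co$subject_id %in% plan$train_ids, ]
  valid <- co[co$subject_id %in% plan$validation_ids, ]
  lpp <- sapply(list(alt, null), function(sp) {
    dt <- build_design(train, sp)
    dr <- suppressWarnings(sample_posterior(dt, prior_spec(), mc, seed = 9))
    log_posterior_predictive(dr, build_design(valid, sp, stats = dt$stats))
  })
  expect_equal(lpp[1] - lpp[2], -(lpp[2] - lpp[1]), tolerance = 1e-12)
  # nesting violations are rejected
  expect_error(cvbf_single_split(co, null, alt, prior_spec(), plan, mc, 1),
               "nested")
})

test_that("aggregation is the geometric mean with a bootstrap interval", {
  co <- small_cohort(n_per_group = 5, seed = 5, acb_time_beta = 0.4)
  alt <- model_spec("PACC5")
  null <- drop_terms(alt, c("acb", "acb_time"))
  mc <- mcmc_control(chains = 1, warmup = 120, draws = 100)
  r <- suppressWarnings(cvbf(co, alt, null, prior_spec(), K = 4, mcmc = mc,
                             seed = 10))
  expect_equal(r$bf, exp(mean(r$log_bf_splits)), tolerance = 1e-12)
  expect_lte(r$ci_lower, r$bf)
  expect_gte(r$ci_upper, r$bf)
  expect_equal(r$category, as.character(categorize_bf(r$bf)))
  expect_equal(nrow(r$splits), 4)
  # deterministic rerun
  r2 <- suppressWarnings(cvbf(co, alt, null, prior_spec(), K = 4, mcmc = mc,
                              seed = 10))
  expect_identical(r$log_bf_splits, r2$log_bf_splits)
  expect_identical(r$ci_lower, r2$ci_lower)
})

test_that("prior sensitivity pairs split plans across priors", {
  co <- small_cohort(n_per_group = 5, seed = 6, acb_time_beta = 0.4)
  alt <- model_spec("PACC5")
  null <- drop_terms(alt, "acb_time")
  mc <- mcmc_control(chains = 1, warmup = 120, draws = 100)
  ps <- suppressWarnings(prior_sensitivity(
    co, alt, null, priors = list(prior_spec("normal_sd_0.5"),
                                 prior_spec("normal_sd_0.5")),
    K = 3, mcmc = mc, seed = 11))
  # identical priors with shared seeds: identical results, ratio exactly 1
  expect_identical(ps$results[[1]]$log_bf_splits,
                   ps$results[[2]]$log_bf_splits)
  expect_equal(ps$max_ratio, 1, tolerance = 1e-12)
  # flat vs informative both execute and categorize
  ps2 <- suppressWarnings(prior_sensitivity(
    co, alt, null, priors = list(prior_spec("flat"),
                                 prior_spec("normal_sd_0.5")),
    K = 2, mcmc = mc, seed = 12))
  expect_true(all(ps2$table$category %in%
                    c("support_null", "weak", "moderate", "strong",
                      "very_strong", "extreme")))
})

test_that("comparison blocks build the three nested pairs", {
  alt <- model_spec("PACC5")
  cb <- comparison_blocks(alt)
  expect_named(cb, c("main", "interaction", "joint"))
  expect_false("acb" %in% cb$main$null$fixed_terms)
  expect_true("acb_time" %in% cb$main$null$fixed_terms)
  expect_false("acb_time" %in% cb$interaction$null$fixed_terms)
  expect_true(all(!c("acb", "acb_time") %in% cb$joint$null$fixed_terms))
})
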