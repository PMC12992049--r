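# Synthetic cohort generator: structure, calibration, determinism, IO.

test_that("group sizes and visit counts are exactly as configured", {
  cfg <- default_sim_config(
    scale = 1, group_sizes = c(CN = 10, SCD = 10), visit_times = 0:3,
    dropout_prob = 0, seed = 5,
    outcome_specs = list(pacc5_gen_spec()))
  co <- generate_cohort(cfg)
  expect_equal(length(unique(co$subject_id)), 20)
  expect_equal(nrow(co), 80)
  tab <- table(unique(co[, c("subject_id", "diagnosis")])$diagnosis)
  expect_equal(as.integer(tab[c("CN", "SCD")]), c(10, 10))
})

test_that("burden-score distributions are calibrated to the target means", {
  p <- acb_probs_for_mean(0.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(p * 0:4), 0.5, tolerance = 1e-9)
  expect_true(which.max(p) == 1) # mass concentrated at zero
  # sampled SCD mean close to the configured 0.5 at n = 5000
  cfg <- default_sim_config(scale = 1, group_sizes = c(CN = 4, SCD = 5000),
                            visit_times = 0, dropout_prob = 0, seed = 7,
                            outcome_specs = list())
  co <- generate_cohort(cfg)
  m <- mean(co$acb_score[co$diagnosis == "SCD"])
  expect_lt(abs(m - 0.5), 0.05)
})

test_that("covariate sample moments converge to the configured moments", {
  cfg <- default_sim_config(scale = 1, group_sizes = c(CN = 5000),
                            visit_times = 0, dropout_prob = 0, seed = 11,
                            outcome_specs = list())
  co <- generate_cohort(cfg)
  n <- nrow(co)
  # 3-standard-error tolerance per moment
  expect_lt(abs(mean(co$age) - 69.2), 3 * 5.3 / sqrt(n))
  expect_lt(abs(sd(co$age) - 5.3), 3 * 5.3 / sqrt(2 * n))
  expect_lt(abs(mean(co$education) - 14.8), 3 * 2.8 / sqrt(n))
  pf <- 97 / 177
  expect_lt(abs(mean(co$sex == "female") - pf),
            3 * sqrt(pf * (1 - pf) / n))
})

test_that("same seed reproduces the cohort byte-identically; seeds differ", {
  cfg <- default_sim_config(scale = 0.05, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  save_cohort(a, f1); save_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- default_sim_config(scale = 0.05, seed = 43)
  expect_false(identical(generate_cohort(cfg2)$PACC5, a$PACC5))
})

test_that("zero-noise outcomes are an exact linear function of covariates", {
  co <- small_cohort(n_per_group = 4, seed = 2)
  spec <- outcome_gen_spec("flatline", beta = c("(Intercept)" = 5),
                           tau_intercept = 0, tau_slope = 0, sigma = 0)
  co2 <- simulate_outcomes(co, spec, seed = 1)
  expect_equal(co2$flatline, rep(5, nrow(co2)))
  # with covariate terms, still exactly deterministic
  spec2 <- outcome_gen_spec("lin", beta = c("(Intercept)" = 1, time = 2,
                                            acb = -0.5),
                            tau_intercept = 0, tau_slope = 0, sigma = 0)
  co3 <- simulate_outcomes(co, spec2, seed = 1)
  expect_equal(co3$lin, 1 + 2 * co3$time - 0.5 * co3$acb_score)
})

test_that("generated trajectories carry the configured burden-by-time slope", {
  # two-arm contrast: burden 0 vs burden 4, slope difference = 4 * beta
  beta_int <- 0.8018
  cfg <- default_sim_config(
    scale = 1, group_sizes = c(SCD = 800), visit_times = 0:4,
    dropout_prob = 0, seed = 13,
    acb_distribution = list(SCD = c(0.5, 0, 0, 0, 0.5)),
    outcome_specs = list(outcome_gen_spec(
      "y", beta = c("(Intercept)" = 0, time = 1, "acb:time" = beta_int),
      tau_intercept = 0.3, tau_slope = 0.1, sigma = 0.3)))
  co <- generate_cohort(cfg)
  slope_of <- function(d) unname(stats::coef(stats::lm(y ~ time, d))["time"])
  diff <- slope_of(co[co$acb_score == 4, ]) - slope_of(co[co$acb_score == 0, ])
  expect_equal(diff, 4 * beta_int, tolerance = 0.05)
})

test_that("random-effect moments match the generative law", {
  co <- small_cohort(n_per_group = 4, seed = 3)
  ids <- unique(co$subject_id)
  tau0 <- 0.9
  spec <- outcome_gen_spec("y", beta = c("(Intercept)" = 0),
                           tau_intercept = tau0, tau_slope = 0, sigma = 0)
  # many independent replicate draws of the same subjects' intercepts
  devs <- unlist(lapply(1:300, function(r) {
    cc <- simulate_outcomes(co, spec, seed = r)
    cc$y[cc$time == 0]
  }))
  expect_lt(abs(stats::var(devs) - tau0^2), 3 * tau0^2 * sqrt(2 / length(devs)))
})

test_that("cohort CSV round-trips bit-exactly and errors are informative", {
  co <- generate_cohort(default_sim_config(scale = 0.04, seed = 9))
  f <- tempfile(fileext = ".csv")
  save_cohort(co, f)
  back <- load_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(co))
  expect_identical(back$PACC5, co$PACC5) # bit-exact numerics

  bad <- co; bad$acb_score[3] <- 2.5
  save_cohort(bad, f)
  expect_error(load_cohort(f), "acb_score.*row.* 3")

  bad2 <- co[co$time > 0 | co$subject_id != co$subject_id[1], ]
  save_cohort(bad2, f)
  expect_error(load_cohort(f), co$subject_id[1])

  incomplete <- co[, setdiff(names(co), "time")]
  utils::write.csv(incomplete, f, row.names = FALSE)
  expect_error(load_cohort(f), "missing required column.*time")
})

test_that("configuration errors name the offending field", {
  expect_error(default_sim_config(
    scale = 0.05, acb_distribution = list(CN = c(0.9, 0.2, 0, 0, 0),
                                          Rel = acb_probs_for_mean(0.14),
                                          SCD = acb_probs_for_mean(0.5),
                                          MCI = acb_probs_for_mean(0.4),
                                          ADD = acb_probs_for_mean(0.5))),
    "acb_distribution\\$CN")
  expect_error(default_sim_config(scale = 0.05, visit_times = c(0, 2, 1)),
               "visit_times")
  expect_error(outcome_gen_spec("y", c("(Intercept)" = 0), tau_intercept = -1,
                                tau_slope = 0, sigma = 1),
               "tau_intercept")
})

test_that("dropout thins follow-up visits but never baseline", {
  cfg <- default_sim_config(scale = 1, group_sizes = c(SCD = 300),
                            visit_times = 0:4, dropout_prob = 0.5, seed = 17,
                            outcome_specs = list())
  co <- generate_cohort(cfg)
  expect_equal(sum(co$time == 0), 300)
  nvisits <- table(co$subject_id)
  # mean retained follow-ups near 4 * 0.5
  expect_lt(abs(mean(nvisits - 1) - 2), 0.25)
})

test_that("missing-outcome fraction is honoured", {
  co <- small_cohort(n_per_group = 30, seed = 4)
  spec <- pacc5_gen_spec(missing_frac = 0.2)
  spec$name <- "with_gaps"
  co2 <- simulate_outcomes(co, spec, seed = 8)
  fr <- mean(is.na(co2$with_gaps))
  expect_gt(fr, 0.12); expect_lt(fr, 0.28)
})
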