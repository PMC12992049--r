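# End-to-end orchestration: simulate -> fit -> cvbf -> report.
#
# Every stage writes plain-text artifacts into the run directory and can be
# re-run standalone on the previous stage's outputs; the staged path and the
# monolithic run produce identical files because all randomness flows from
# the master seed through named substreams.

#' Load and validate a run configuration
#'
#' A run configuration describes one full analysis: where the cohort comes
#' from (a CSV or the synthetic generator), which outcomes to analyse,
#' which priors and model comparisons to run, split and MCMC settings, and
#' the master seed. Accepts a YAML/JSON file path or a named list.
#'
#' @param config file path or named list. Recognised fields:
#'   `output_dir`, `seed`, `cohort_csv` (optional), `simulation$scale`,
#'   `outcomes`, `priors`, `blocks`, `K`, `train_fraction`,
#'   `apoe_sensitivity`, `mcmc` (`chains`, `warmup`, `draws`).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(output_dir = "cvbf_run", seed = 1L, cohort_csv = NULL,
                   simulation = list(scale = 0.25),
                   outcomes = c("PACC5", "TMTB"),
                   priors = "normal_sd_0.5",
                   blocks = c("main", "interaction"),
                   K = 10L, train_fraction = 0.5, apoe_sensitivity = FALSE,
                   mcmc = list(chains = 2L, warmup = 400L, draws = 400L))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$outcomes) == 0) stop_config("config: 'outcomes' must be non-empty")
  bad_priors <- setdiff(cfg$priors, c("normal_sd_0.5", "normal_sd_1", "flat"))
  if (length(bad_priors) > 0)
    stop_config("config: unknown prior(s): %s", paste(bad_priors, collapse = ", "))
  bad_blocks <- setdiff(cfg$blocks, c("main", "interaction", "joint"))
  if (length(bad_blocks) > 0)
    stop_config("config: unknown comparison block(s): %s",
                paste(bad_blocks, collapse = ", "))
  if (cfg$K < 2) stop_config("config: K must be >= 2")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop_config("config: train_fraction must lie strictly between 0 and 1")
  if (is.null(cfg$seed)) stop_config("config: a master 'seed' is required")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

run_log <- function(out_dir, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"), append = TRUE)
}

pipeline_mcmc <- function(cfg) {
  mcmc_control(chains = cfg$mcmc$chains, warmup = cfg$mcmc$warmup,
               draws = cfg$mcmc$draws)
}

alt_spec_for <- function(outcome, with_apoe = FALSE) {
  terms <- c("time", "acb", "acb_time", "diagnosis", "diagnosis_time",
             "sex", "age", "education")
  if (with_apoe) terms <- c(terms, "apoe4", "apoe4_time")
  model_spec(outcome, terms)
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` writes `cohort.csv` (generated, or loaded and
#' validated from `cohort_csv`); `"fit"` writes full-data parameter
#' estimates under the N(0, 0.5) prior (plus an ApoE-augmented refit when
#' configured); `"cvbf"` writes the evidence and per-split tables for every
#' outcome x prior x comparison block; `"report"` writes the JSON manifest
#' tying the bundle together. Each stage reads only the previous stage's
#' on-disk outputs.
#'
#' @param stage one of `"simulate"`, `"fit"`, `"cvbf"`, `"report"`.
#' @param config a [run_config()] (or path/list coercible to one).
#' @return invisibly, stage-specific results.
#' @export
run_stage <- function(stage = c("simulate", "fit", "cvbf", "report"), config) {
  stage <- match.arg(stage)
  cfg <- run_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(out_dir, "cohort.csv")

  need_cohort <- function() {
    if (!file.exists(cohort_path))
      stop_config("missing upstream artifact '%s'; run the 'simulate' stage first",
                  cohort_path)
    cohort <- load_cohort(cohort_path)
    missing_out <- setdiff(cfg$outcomes, names(cohort))
    if (length(missing_out) > 0)
      stop_config("config: outcome column(s) not in cohort: %s",
                  paste(missing_out, collapse = ", "))
    cohort
  }

  if (stage == "simulate") {
    t0 <- Sys.time()
    if (!is.null(cfg$cohort_csv)) {
      cohort <- load_cohort(cfg$cohort_csv)
    } else {
      sim_seed <- substream_seed(cfg$seed, "simulate")
      cohort <- generate_cohort(default_sim_config(
        scale = cfg$simulation$scale, seed = sim_seed))
    }
    save_cohort(cohort, cohort_path)
    run_log(out_dir, "[simulate] %d subjects, %d rows (%.1fs)",
            length(unique(cohort$subject_id)), nrow(cohort),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    return(invisible(cohort))
  }

  if (stage == "fit") {
    cohort <- need_cohort()
    summaries <- list()
    for (o in cfg$outcomes) {
      t0 <- Sys.time()
      spec <- alt_spec_for(o)
      design <- build_design(cohort, spec)
      draws <- sample_posterior(design, prior_spec("normal_sd_0.5"),
                                pipeline_mcmc(cfg),
                                seed = substream_seed(cfg$seed, paste0("fit:", o)))
      summaries[[o]] <- summarize_posterior(draws, design)
      run_log(out_dir,
              "[fit] %s: %d rows (%d dropped), max Rhat %.3f (%.1fs)",
              o, design$n_rows, design$dropped_rows,
              max(draws$diagnostics$rhat, na.rm = TRUE),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
      if (isTRUE(cfg$apoe_sensitivity)) {
        spec2 <- alt_spec_for(o, with_apoe = TRUE)
        design2 <- build_design(cohort, spec2)
        draws2 <- sample_posterior(design2, prior_spec("normal_sd_0.5"),
                                   pipeline_mcmc(cfg),
                                   seed = substream_seed(cfg$seed,
                                                         paste0("fit_apoe:", o)))
        summaries[[paste0(o, "+apoe4")]] <- summarize_posterior(draws2, design2)
        run_log(out_dir, "[fit] %s + ApoE sensitivity refit done", o)
      }
    }
    est <- do.call(rbind, lapply(names(summaries), function(o)
      cbind(data.frame(outcome = o, stringsAsFactors = FALSE),
            as.data.frame(summaries[[o]]))))
    write_full_precision_csv(est, file.path(out_dir, "parameter_estimates.csv"))
    return(invisible(summaries))
  }

  if (stage == "cvbf") {
    cohort <- need_cohort()
    results <- list()
    for (o in cfg$outcomes) {
      pairs <- comparison_blocks(alt_spec_for(o), cfg$blocks)
      for (bl in names(pairs)) {
        # the seed excludes the prior so split plans are paired across priors
        seed_ob <- substream_seed(cfg$seed, paste0("cvbf:", o, ":", bl))
        for (pk in cfg$priors) {
          t0 <- Sys.time()
          r <- cvbf(cohort, pairs[[bl]]$alt, pairs[[bl]]$null,
                    prior_spec(pk), K = cfg$K,
                    train_fraction = cfg$train_fraction,
                    mcmc = pipeline_mcmc(cfg), seed = seed_ob,
                    comparison = bl)
          results[[paste(o, bl, pk, sep = "|")]] <- r
          run_log(out_dir, "[cvbf] %s %s %s: CV-BF %.3g -> %s (%.1fs)",
                  o, bl, pk, r$bf, r$category,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")))
        }
      }
    }
    rpt <- build_report(results, out_dir = out_dir,
                        manifest = pipeline_manifest(cfg))
    return(invisible(results))
  }

  # report: re-emit the manifest and check the bundle is complete
  expected <- c("cohort.csv", "parameter_estimates.csv", "cvbf_evidence.csv",
                "cvbf_splits.csv")
  missing <- expected[!file.exists(file.path(out_dir, expected))]
  if (length(missing) > 0)
    stop_config("missing upstream artifact(s): %s; run earlier stages first",
                paste(file.path(out_dir, missing), collapse = ", "))
  jsonlite::write_json(pipeline_manifest(cfg),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(out_dir, "[report] bundle complete in %s", out_dir)
  invisible(file.path(out_dir, "manifest.json"))
}

pipeline_manifest <- function(cfg) {
  list(seed = cfg$seed, outcomes = cfg$outcomes, priors = cfg$priors,
       blocks = cfg$blocks, K = cfg$K, train_fraction = cfg$train_fraction,
       apoe_sensitivity = isTRUE(cfg$apoe_sensitivity), mcmc = cfg$mcmc,
       simulation_scale = if (is.null(cfg$cohort_csv)) cfg$simulation$scale
                          else NULL,
       cohort_csv = cfg$cohort_csv,
       package_version = as.character(utils::packageVersion("cvbflmm")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, fit, cvbf and report in sequence, writing the full
#' report bundle (cohort CSV, parameter estimates, evidence and per-split
#' tables, JSON manifest, run log) into the configured output directory.
#'
#' @param config a [run_config()] (or path/list coercible to one).
#' @param output_dir,seed optional overrides of the configured values.
#' @return invisibly, the output directory.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(output_dir = tempfile(), seed = 7,
#'                          simulation = list(scale = 0.05),
#'                          outcomes = "PACC5", blocks = "joint", K = 2,
#'                          mcmc = list(chains = 1, warmup = 150, draws = 150)))
#' }
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  cfg <- run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  for (stage in c("simulate", "fit", "cvbf", "report")) {
    run_stage(stage, cfg)
  }
  invisible(cfg$output_dir)
}
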