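# Shared calibration experiments for the CVBF operating characteristics:
# replicate cohorts with a known burden-by-time effect, CVBF of the joint
# burden comparison on each. Computed lazily and cached so several tests
# can reuse the same runs.

.calibration_cache <- new.env(parent = emptyenv())

# aggregate log CVBF for n_rep replicate cohorts at a given true
# burden-by-time effect (outcome is a unit-SD-scale composite, so the
# effect is in SD per year per burden point)
calibration_log_cvbfs <- function(effect, n_rep, seed_base = 2000) {
  key <- sprintf("eff%g_n%d", effect, n_rep)
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  alt <- model_spec("PACC5")
  null <- drop_terms(alt, c("acb", "acb_time"))
  mc <- mcmc_control(chains = 1, warmup = 250, draws = 250)
  out <- vapply(seq_len(n_rep), function(r) {
    co <- small_cohort(n_per_group = 12, n_visits = 4,
                       seed = seed_base + r,
                       acb_beta = 0, acb_time_beta = effect)
    res <- suppressWarnings(
      cvbf(co, alt, null, prior_spec("normal_sd_0.5"), K = 5, mcmc = mc,
           seed = seed_base + 100 + r, comparison = "joint"))
    mean(res$log_bf_splits)
  }, numeric(1))
  .calibration_cache[[key]] <- out
  out
}
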