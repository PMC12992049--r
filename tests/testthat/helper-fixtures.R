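# Shared fixtures: small cohorts and reference implementations used as
# independent oracles.

# balanced five-group cohort, complete annual visits, PACC5-like outcome
small_cohort <- function(n_per_group = 12, n_visits = 4, seed = 1,
                         acb_beta = 0, acb_time_beta = 0, ...) {
  spec <- pacc5_gen_spec(acb_beta = acb_beta, acb_time_beta = acb_time_beta, ...)
  cfg <- default_sim_config(
    scale = 1, outcome_specs = list(spec), seed = seed,
    group_sizes = c(CN = n_per_group, Rel = n_per_group, SCD = n_per_group,
                    MCI = n_per_group, ADD = n_per_group),
    visit_times = seq(0, n_visits - 1),
    dropout_prob = 0)
  generate_cohort(cfg)
}

# brute-force Monte-Carlo marginalization over a subject's random effects
mc_subject_loglik <- function(draw, X, times, y, n_mc = 1e5, seed = 99) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n_mc), n_mc, 2)
  rho <- draw$rho
  b0 <- draw$tau0 * z[, 1]
  b1 <- draw$tau1 * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  mu <- as.vector(rbind(X) %*% draw$beta)
  ll <- numeric(n_mc)
  for (j in seq_along(y)) {
    ll <- ll + stats::dnorm(y[j], mu[j] + b0 + b1 * times[j], draw$sigma,
                            log = TRUE)
  }
  cvbflmm:::logsumexp(ll) - log(n_mc)
}

# closed-form Gaussian-conjugate (ridge) posterior for the
# fixed-effects-only model with known residual SD
conjugate_posterior <- function(X, y, sigma, prior_sd) {
  A <- crossprod(X) / sigma^2 + diag(1 / prior_sd^2, ncol(X))
  V <- solve(A)
  list(mean = as.vector(V %*% crossprod(X, y)) / sigma^2, cov = V)
}
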