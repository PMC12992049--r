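# Collapsed Metropolis-within-Gibbs sampler for the Gaussian
# random-intercept-and-slope model.
#
# The subject random effects AND the fixed-effect vector are integrated out
# analytically, leaving a 4-dimensional marginal posterior over
# (tau0, tau1, rho, sigma) that is explored by adaptive random-walk
# Metropolis on unconstrained coordinates; the fixed effects are then drawn
# from their exact Gaussian conditional. This avoids the funnel pathologies
# of sampling random effects directly and mixes well even when the true
# variance components are at or near zero.

#' MCMC settings
#'
#' @param chains number of independent chains.
#' @param warmup adaptation iterations discarded per chain.
#' @param draws retained post-warmup iterations per chain.
#' @param fix optional named list fixing variance components (any of
#'   `tau0`, `tau1`, `rho`, `sigma`) at known values instead of sampling
#'   them, e.g. `fix = list(tau0 = 0, tau1 = 0, sigma = 1)` for a
#'   fixed-effects-only model with known residual SD.
#' @param init optional named list of initial values for the sampled
#'   variance components.
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2L, warmup = 400L, draws = 400L,
                         fix = list(), init = NULL) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1)
  bad <- setdiff(names(fix), c("tau0", "tau1", "rho", "sigma"))
  if (length(bad) > 0)
    stop_config("mcmc fix: unknown parameter(s) %s", paste(bad, collapse = ", "))
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), fix = fix, init = init),
            class = "mcmc_control")
}

# log prior of the variance components on the unconstrained scale,
# including Jacobians: half-normal(0, scale) on tau0, tau1, sigma;
# uniform(-1, 1) on rho.
theta_log_prior <- function(tau0, tau1, rho, sigma, scale, free) {
  lp <- 0
  hn <- function(v) -v^2 / (2 * scale^2) + log(v) # log half-normal + log Jacobian
  if (free["tau0"]) lp <- lp + hn(tau0)
  if (free["tau1"]) lp <- lp + hn(tau1)
  if (free["sigma"]) lp <- lp + hn(sigma)
  if (free["rho"]) lp <- lp + log1p(-rho^2)       # Jacobian of atanh
  lp
}

check_design_ok <- function(design) {
  X <- design$X
  p <- ncol(X)
  if (p >= nrow(X))
    stop_config("degenerate design: %d fixed-effect columns for %d rows", p, nrow(X))
  nvisits <- design$ends - design$starts + 1L
  if (sum(nvisits >= 2) < 2)
    stop_config("degenerate design: need at least 2 subjects with 2+ visits")
  qd <- qr(X)
  if (qd$rank < p) {
    dep <- design$col_names[qd$pivot[(qd$rank + 1):p]]
    stop_config("collinear design column(s): %s", paste(dep, collapse = ", "))
  }
  invisible(TRUE)
}

#' Draw from the posterior of the linear mixed model
#'
#' Samples `(beta, tau0, tau1, rho, sigma)` under the priors of a
#' [prior_spec()]: independent normals with mean zero and common SD on the
#' fixed effects (standardized scale), half-normal(0, 2.5) on the three
#' standard deviations, uniform on the intercept-slope correlation.
#' Reproducible under a fixed seed. Emits split-chain scale-reduction
#' diagnostics and warns when any exceeds 1.05.
#'
#' @param design an [build_design()] result.
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed.
#' @return an object of class `posterior_draws` with elements `beta`
#'   (draws x p matrix), `tau0`, `tau1`, `rho`, `sigma`, `lp` (joint
#'   unnormalized log posterior per draw), `chain`, and `diagnostics`.
#' @export
sample_posterior <- function(design, prior = prior_spec(), mcmc = mcmc_control(),
                             seed = 1L) {
  stopifnot(inherits(design, "lmm_design"), inherits(prior, "prior_spec"))
  check_design_ok(design)
  X <- design$X
  y <- design$y
  p <- ncol(X)
  starts0 <- design$starts - 1L
  ends0 <- design$ends - 1L
  s_beta <- prior$beta_sd
  free <- c(tau0 = TRUE, tau1 = TRUE, rho = TRUE, sigma = TRUE)
  fixed_vals <- c(tau0 = NA_real_, tau1 = NA_real_, rho = NA_real_,
                  sigma = NA_real_)
  for (nm in names(mcmc$fix)) {
    free[nm] <- FALSE
    fixed_vals[nm] <- mcmc$fix[[nm]]
  }

  loglik_at <- function(th, want_beta = FALSE) {
    cpp_collapsed_loglik(y, X, starts0, ends0, design$times,
                         th["tau0"], th["tau1"], th["rho"], th["sigma"],
                         s_beta, want_beta)
  }

  n_iter <- mcmc$warmup + mcmc$draws
  all_beta <- vector("list", mcmc$chains)
  all_theta <- vector("list", mcmc$chains)
  accept_rates <- matrix(NA_real_, mcmc$chains, 4,
                         dimnames = list(NULL, names(free)))

  for (ch in seq_len(mcmc$chains)) {
    set.seed(substream_seed(seed, "chain", ch))
    th <- c(tau0 = 0.5, tau1 = 0.1, rho = 0, sigma = 0.8)
    for (nm in names(mcmc$init %||% list())) th[nm] <- mcmc$init[[nm]]
    th[!free] <- fixed_vals[!free]
    # unconstrained state for the free coordinates
    to_con <- function(u) c(tau0 = exp(u[[1]]), tau1 = exp(u[[2]]),
                            rho = tanh(u[[3]]), sigma = exp(u[[4]]))
    u <- c(log(max(th["tau0"], 1e-4)), log(max(th["tau1"], 1e-4)),
           atanh(min(max(th["rho"], -0.99), 0.99)), log(max(th["sigma"], 1e-4)))
    names(u) <- names(free)
    scales <- c(0.5, 0.5, 0.5, 0.3)
    names(scales) <- names(free)
    cur_con <- to_con(u)
    cur_con[!free] <- fixed_vals[!free]
    cur_lp <- loglik_at(cur_con)$loglik +
      theta_log_prior(cur_con["tau0"], cur_con["tau1"], cur_con["rho"],
                      cur_con["sigma"], prior$tau_scale, free)
    n_acc <- n_try <- setNames(numeric(4), names(free))

    beta_mat <- matrix(NA_real_, mcmc$draws, p)
    theta_mat <- matrix(NA_real_, mcmc$draws, 4,
                        dimnames = list(NULL, names(free)))
    for (it in seq_len(n_iter)) {
      for (k in names(free)[free]) {
        u_prop <- u
        u_prop[k] <- u[k] + scales[k] * rnorm(1)
        con_prop <- to_con(u_prop)
        con_prop[!free] <- fixed_vals[!free]
        lp_prop <- loglik_at(con_prop)$loglik +
          theta_log_prior(con_prop["tau0"], con_prop["tau1"], con_prop["rho"],
                          con_prop["sigma"], prior$tau_scale, free)
        acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - cur_lp
        if (acc) {
          u <- u_prop; cur_con <- con_prop; cur_lp <- lp_prop
        }
        n_try[k] <- n_try[k] + 1
        n_acc[k] <- n_acc[k] + acc
        if (it <= mcmc$warmup) {
          scales[k] <- scales[k] * exp((acc - 0.44) / sqrt(n_try[k]))
        }
      }
      if (it > mcmc$warmup) {
        piece <- loglik_at(cur_con, want_beta = TRUE)
        z <- rnorm(p)
        # beta = m + (L^-T) z with A = L L' the posterior precision
        beta <- piece$post_mean +
          backsolve(t(piece$chol_prec_lower), z)
        s <- it - mcmc$warmup
        beta_mat[s, ] <- beta
        theta_mat[s, ] <- cur_con
      }
    }
    accept_rates[ch, ] <- ifelse(n_try > 0, n_acc / n_try, NA_real_)
    all_beta[[ch]] <- beta_mat
    all_theta[[ch]] <- theta_mat
  }

  beta <- do.call(rbind, all_beta)
  colnames(beta) <- design$col_names
  theta <- do.call(rbind, all_theta)
  chain <- rep(seq_len(mcmc$chains), each = mcmc$draws)

  # joint unnormalized log posterior per stored draw
  drawmat <- cbind(beta, theta)
  cond_ll <- cpp_predictive_totals(drawmat, y, X, starts0, ends0, design$times)
  lp <- cond_ll +
    rowSums(-0.5 * (beta / s_beta)^2) - p * log(s_beta) +
    vapply(seq_len(nrow(theta)), function(i)
      theta_log_prior(theta[i, "tau0"], theta[i, "tau1"], theta[i, "rho"],
                      theta[i, "sigma"], prior$tau_scale, free) -
        (if (free["tau0"]) log(theta[i, "tau0"]) else 0) -
        (if (free["tau1"]) log(theta[i, "tau1"]) else 0) -
        (if (free["sigma"]) log(theta[i, "sigma"]) else 0) -
        (if (free["rho"]) log1p(-theta[i, "rho"]^2) else 0),
      numeric(1))

  pars <- cbind(beta, theta)
  rhat <- apply(pars, 2, split_rhat, chain = chain)
  if (any(is.finite(rhat) & rhat > 1.05)) {
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f (%s)",
                    max(rhat, na.rm = TRUE),
                    colnames(pars)[which.max(rhat)]), call. = FALSE)
  }

  structure(list(beta = beta, tau0 = theta[, "tau0"], tau1 = theta[, "tau1"],
                 rho = theta[, "rho"], sigma = theta[, "sigma"], lp = lp,
                 chain = chain, col_names = design$col_names,
                 prior = prior, mcmc = mcmc, seed = seed,
                 diagnostics = list(rhat = rhat, accept_rates = accept_rates)),
            class = "posterior_draws")
}

# split-chain potential scale reduction (rank-free, classic formula on
# split halves)
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    if (h < 2) return(NULL)
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  })
  segs <- do.call(c, halves[!vapply(halves, is.null, logical(1))])
  if (length(segs) < 2) return(NA_real_)
  m <- length(segs); n <- length(segs[[1]])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(ifelse(B <= 1e-300, 1, Inf))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws x %d chains, %d fixed effects (prior %s)\n",
              length(x$tau0) / max(x$chain), max(x$chain),
              ncol(x$beta), x$prior$kind))
  cat(sprintf("  max split-Rhat: %.3f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Summarize fixed effects on the original outcome scale
#'
#' Posterior means and central 95% credible intervals per fixed-effect
#' term, mapped back from the standardized fitting scale to original
#' outcome and covariate units via the exact linear transformation stored
#' in the design. A term is flagged when its interval excludes zero.
#'
#' @param draws a [sample_posterior()] result.
#' @param design the design the draws were generated from.
#' @param level credible level (default 0.95).
#' @return a `data.frame` of class `parameter_summary` with columns `term`,
#'   `estimate`, `ci_lower`, `ci_upper`, `excludes_zero`; random-effect and
#'   residual SD summaries (original outcome units) are attached as
#'   attribute `"variance_components"`.
#' @export
summarize_posterior <- function(draws, design, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(design, "lmm_design"))
  if (nrow(draws$beta) == 0) stop_config("no posterior draws to summarize")
  a <- (1 - level) / 2
  raw <- draws$beta %*% t(design$transform) * design$y_scale
  colnames(raw) <- design$col_names
  ic <- match("(Intercept)", design$col_names)
  if (!is.na(ic)) raw[, ic] <- raw[, ic] + design$y_center
  est <- colMeans(raw)
  qs <- apply(raw, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(term = design$col_names, estimate = unname(est),
                    ci_lower = qs[1, ], ci_upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$excludes_zero <- out$ci_lower > 0 | out$ci_upper < 0
  vc <- data.frame(
    component = c("tau_intercept", "tau_slope", "re_correlation", "sigma"),
    estimate = c(mean(draws$tau0) * design$y_scale,
                 mean(draws$tau1) * design$y_scale,
                 mean(draws$rho),
                 mean(draws$sigma) * design$y_scale),
    stringsAsFactors = FALSE)
  attr(out, "variance_components") <- vc
  class(out) <- c("parameter_summary", "data.frame")
  out
}
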