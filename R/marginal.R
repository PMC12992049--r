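# Closed-form held-out likelihoods with random effects marginalized.

#' Marginal log likelihood of one subject's data under a single draw
#'
#' For a (possibly held-out) subject with design rows `X_i`, visit times
#' `t_i` and responses `y_i`, integrates the unobserved random intercept
#' and slope analytically:
#' `log N(y_i | X_i beta, Z_i G Z_i' + sigma^2 I)` with
#' `Z_i = [1, t_i]` and `G` the 2x2 random-effect covariance implied by
#' `(tau0, tau1, rho)`. Computed via a Cholesky factorization of the
#' per-subject covariance for numerical stability.
#'
#' @param draw list with elements `beta` (length-p vector matching the
#'   columns of `X`), `tau0`, `tau1`, `rho`, `sigma`.
#' @param X n_i x p fixed-effect design for the subject.
#' @param times length-n_i visit times.
#' @param y length-n_i responses.
#' @return the marginal log density (scalar).
#' @export
subject_marginal_loglik <- function(draw, X, times, y) {
  X <- rbind(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(times) == n, ncol(X) == length(draw$beta))
  g00 <- draw$tau0^2
  g01 <- draw$rho * draw$tau0 * draw$tau1
  g11 <- draw$tau1^2
  V <- g00 + g01 * outer(times, times, `+`) + g11 * outer(times, times) +
    diag(draw$sigma^2, n)
  bad <- function() stop_config(
    "subject covariance is not positive definite (tau0=%g, tau1=%g, rho=%g, sigma=%g)",
    draw$tau0, draw$tau1, draw$rho, draw$sigma)
  if (any(!is.finite(V))) bad()
  L <- tryCatch(chol(V), error = function(e) bad())
  if (any(!is.finite(diag(L))) || any(diag(L) <= 0)) bad()
  r <- y - as.vector(X %*% draw$beta)
  w <- forwardsolve(t(L), r)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w^2)
}

#' Held-out posterior predictive log density
#'
#' The log of the posterior-averaged likelihood of a validation set under a
#' model fitted to training data: each draw's total validation log
#' likelihood sums closed-form subject marginals (held-out subjects' random
#' effects integrated out), and the average over draws is taken with
#' log-sum-exp so it never overflows.
#'
#' @param draws a [sample_posterior()] result (from the training fit).
#' @param design validation design built with the TRAINING statistics:
#'   `build_design(validation_cohort, spec, stats = training_design$stats)`.
#' @param method `"cpp"` (default, batched) or `"r"` (reference
#'   implementation looping over [subject_marginal_loglik()]).
#' @return `log[(1/S) * sum_s exp(total_s)]`, a scalar.
#' @export
log_posterior_predictive <- function(draws, design, method = c("cpp", "r")) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(design, "lmm_design"))
  method <- match.arg(method)
  if (!identical(colnames(draws$beta), design$col_names))
    stop_config("draw coefficients do not match the validation design columns")
  totals <- predictive_totals(draws, design, method)
  logsumexp(totals) - log(length(totals))
}

# per-draw total validation log likelihood
predictive_totals <- function(draws, design, method = c("cpp", "r")) {
  method <- match.arg(method)
  if (method == "cpp") {
    drawmat <- cbind(draws$beta, draws$tau0, draws$tau1, draws$rho, draws$sigma)
    return(as.vector(cpp_predictive_totals(
      drawmat, design$y, design$X, design$starts - 1L, design$ends - 1L,
      design$times)))
  }
  S <- nrow(draws$beta)
  vapply(seq_len(S), function(s) {
    d <- list(beta = draws$beta[s, ], tau0 = draws$tau0[s],
              tau1 = draws$tau1[s], rho = draws$rho[s], sigma = draws$sigma[s])
    tot <- 0
    for (i in seq_along(design$starts)) {
      rr <- design$starts[i]:design$ends[i]
      tot <- tot + subject_marginal_loglik(
        d, design$X[rr, , drop = FALSE], design$times[rr], design$y[rr])
    }
    tot
  }, numeric(1))
}
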