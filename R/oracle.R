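## Exhaustive-enumeration posteriors used to validate the Gibbs sampler.
## Both oracles share the sampler's prior object so that any disagreement
## points at the sampler, never at a prior mismatch.

model_bitstrings <- function(p) {
  if (p == 0L) return("")
  ## character j of each bitstring is the inclusion indicator of analyte j
  apply(as.matrix(expand.grid(rep(list(0:1), p))), 1L, paste, collapse = "")
}

exact_posterior <- function(models, log_marg, prior, p, analytes) {
  log_prior <- vapply(models, function(m) {
    g <- as.integer(strsplit(m, "")[[1L]])
    sum(g) * log(prior$pi) + (p - sum(g)) * log1p(-prior$pi)
  }, numeric(1))
  lp <- log_marg + log_prior
  prob <- exp(lp - logsumexp(lp))
  prob <- prob / sum(prob)
  rho <- if (p > 0L) {
    gmat <- matrix(unlist(lapply(models, function(m)
      as.integer(strsplit(m, "")[[1L]]))), ncol = p, byrow = TRUE)
    as.numeric(crossprod(gmat, prob))
  } else numeric(0)
  structure(list(models = models, log_marginal = log_marg,
                 prob = stats::setNames(prob, models),
                 rho = stats::setNames(rho, analytes), prior = prior),
            class = "exact_posterior")
}

#' Exact model posterior by enumeration (linear outcome)
#'
#' Enumerates all 2^p models. Under a normal slab of variance `tau2` on each
#' included coefficient, a vague normal intercept, and unit residual
#' variance, each model's marginal likelihood of the real-valued response is
#' Gaussian and evaluated in closed form via the low-rank determinant and
#' Woodbury identities; model probabilities combine these with the
#' Bernoulli(`pi`) model prior.
#'
#' @param design a [standardize_design()] result with a real-valued `$y`.
#' @param prior a [selection_prior()].
#' @return An object of class `exact_posterior`: per-model probabilities
#'   (named by bitstring) and exact per-analyte inclusion probabilities
#'   `$rho`.
#' @export
enumerate_linear <- function(design, prior = selection_prior()) {
  X <- design$X
  y <- as.numeric(design$y)
  n <- length(y)
  p <- ncol(X)
  if (p > 12L) stopf("enumeration limited to p <= 12 (2^p models)")
  W <- cbind(`(intercept)` = 1, X)
  G <- crossprod(W)
  Wty <- as.numeric(crossprod(W, y))
  yty <- sum(y^2)
  models <- model_bitstrings(p)
  log_marg <- vapply(models, function(m) {
    g <- if (p > 0L) as.integer(strsplit(m, "")[[1L]]) else integer(0)
    idx <- c(1L, which(g == 1L) + 1L)
    vars <- c(prior$intercept_var, rep(prior$tau2, sum(g)))
    M <- G[idx, idx, drop = FALSE] + diag(1 / vars, length(idx))
    R <- chol(M)
    u <- forwardsolve(t(R), Wty[idx])
    logdet_sigma <- sum(log(vars)) + 2 * sum(log(diag(R)))
    quad <- yty - sum(u^2)
    -n / 2 * log(2 * pi) - 0.5 * logdet_sigma - 0.5 * quad
  }, numeric(1))
  exact_posterior(models, log_marg, prior, p, colnames(X))
}

## negative log of the probit integrand (likelihood x prior density) for one
## model; th = c(alpha, beta_included)
probit_negloglik <- function(th, Xs, sgn, vars) {
  eta <- th[1L] + if (length(th) > 1L)
    as.numeric(Xs %*% th[-1L]) else 0
  ll <- sum(stats::pnorm(sgn * eta, log.p = TRUE))
  -ll + sum(th^2 / (2 * vars)) + 0.5 * sum(log(2 * pi * vars))
}

probit_negloglik_grad <- function(th, Xs, sgn, vars) {
  eta <- th[1L] + if (length(th) > 1L)
    as.numeric(Xs %*% th[-1L]) else 0
  ## d/d eta log Phi(s eta) = s phi(eta) / Phi(s eta)
  r <- sgn * exp(stats::dnorm(eta, log = TRUE) -
                   stats::pnorm(sgn * eta, log.p = TRUE))
  g_eta <- -r
  g <- c(sum(g_eta), if (length(th) > 1L) as.numeric(crossprod(Xs, g_eta)))
  g + th / vars
}

#' Exact model posterior by adaptive quadrature (probit outcome)
#'
#' Enumerates all 2^p probit models (p <= 3) and computes each marginal
#' likelihood by integrating the probit likelihood against the normal priors
#' on the intercept and the included coefficients, using Gauss-Hermite
#' quadrature adapted at the posterior mode with Hessian rescaling. The node
#' count is refined once and the two estimates must agree to `tol` on the
#' log scale, otherwise an error names the offending model.
#'
#' @param design a [standardize_design()] result with a 0/1 `$y`.
#' @param prior a [selection_prior()].
#' @param gh_nodes Gauss-Hermite nodes per dimension for the first pass.
#' @param tol convergence tolerance on the log marginal likelihood between
#'   the two node counts.
#' @return An `exact_posterior`; see [enumerate_linear()].
#' @export
enumerate_probit_quadrature <- function(design, prior = selection_prior(),
                                        gh_nodes = 12L, tol = 1e-4) {
  X <- design$X
  y <- as.numeric(design$y)
  n <- length(y)
  p <- ncol(X)
  if (p > 3L) stopf("probit quadrature limited to p <= 3")
  if (n > 2000L) stopf("probit quadrature limited to n <= 2000")
  sgn <- 2 * y - 1
  models <- model_bitstrings(p)
  log_marg <- vapply(models, function(m) {
    g <- if (p > 0L) as.integer(strsplit(m, "")[[1L]]) else integer(0)
    Xs <- X[, which(g == 1L), drop = FALSE]
    vars <- c(prior$intercept_var, rep(prior$tau2, sum(g)))
    k <- length(vars)
    opt <- stats::optim(rep(0, k), probit_negloglik, probit_negloglik_grad,
                        Xs = Xs, sgn = sgn, vars = vars, method = "BFGS",
                        control = list(maxit = 200L))
    H <- stats::optimHess(opt$par, probit_negloglik, probit_negloglik_grad,
                          Xs = Xs, sgn = sgn, vars = vars)
    est <- vapply(c(gh_nodes, gh_nodes + 4L), function(nn)
      gh_log_integral(opt$par, H, nn, function(theta)
        -apply(theta, 1L, probit_negloglik, Xs = Xs, sgn = sgn, vars = vars)),
      numeric(1))
    if (abs(est[1L] - est[2L]) > tol)
      stopf("quadrature did not converge for model '%s' (delta %.2e)",
            m, abs(est[1L] - est[2L]))
    est[2L]
  }, numeric(1))
  exact_posterior(models, log_marg, prior, p, colnames(X))
}

## log of integral exp(logf(theta)) d theta by Gauss-Hermite quadrature
## adapted at `mode` with Hessian `H` of -logf
gh_log_integral <- function(mode, H, nn, logf) {
  k <- length(mode)
  gh <- pracma::gaussHermite(nn)
  R <- chol((H + t(H)) / 2)
  A <- backsolve(R, diag(k))         # A A' = H^{-1}
  grid <- as.matrix(expand.grid(rep(list(gh$x), k)))
  logw <- as.matrix(expand.grid(rep(list(log(gh$w)), k)))
  theta <- sweep(sqrt(2) * grid %*% t(A), 2L, mode, "+")
  lf <- logf(theta)
  terms <- rowSums(logw) + rowSums(grid^2) + lf
  k / 2 * log(2) - sum(log(diag(R))) + logsumexp(terms)
}

#' @export
print.exact_posterior <- function(x, ...) {
  cat(sprintf("<exact_posterior> %d models enumerated\n", length(x$models)))
  if (length(x$rho)) print(round(x$rho, 4))
  invisible(x)
}
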