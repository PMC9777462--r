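#' Standardize a design matrix
#'
#' Centers every column to mean zero and scales it to unit variance, storing
#' the per-analyte centring and scaling so that coefficients can be reported
#' back in native units. Heterogeneous analyte units make a common scale a
#' prerequisite for a shared slab prior.
#'
#' @param x numeric matrix (cases x analytes) with named columns.
#' @param y optional response vector (binary diagnosis for the probit
#'   sampler, real-valued for the linear variant).
#' @return An object of class `design_matrix` with elements `X` (standardized
#'   columns), `center`, `scale` and `y`.
#' @export
standardize_design <- function(x, y = NULL) {
  if (inherits(x, "lab_matrix")) x <- x$values
  if (!is.matrix(x)) x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  ctr <- colMeans(x)
  X <- sweep(sweep(x, 2L, ctr), 2L, sds, "/")
  structure(list(X = X, center = ctr, scale = sds, y = y),
            class = "design_matrix")
}

#' Orthogonal data augmentation of a design matrix
#'
#' Appends p pseudo-rows `X_a` so that the combined Gram matrix
#' `X_o' X_o + X_a' X_a` equals `diag(D)` with
#' `D = (lambda_max(X_o' X_o) + epsilon) * 1_p`. The completion
#' `diag(D) - X_o' X_o` is positive definite by construction (its smallest
#' eigenvalue is `epsilon`), and its upper-triangular Cholesky factor is the
#' augmentation. A diagonal combined Gram matrix decouples the coordinates of
#' the Gibbs sampler.
#'
#' @param X_o standardized n x p design matrix (or a `design_matrix`).
#' @param epsilon positive ridge inflation added to the spectral radius;
#'   default `0.001 * lambda_max`.
#' @return An object of class `augmented_design` with elements `X_a`, `D`
#'   (length-p vector) and `epsilon`.
#' @export
orthogonal_augment <- function(X_o, epsilon = NULL) {
  if (inherits(X_o, "design_matrix")) X_o <- X_o$X
  p <- ncol(X_o)
  if (p < 1L) stopf("design must have at least one column")
  G <- crossprod(X_o)
  lmax <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  epsilon <- epsilon %||% (0.001 * lmax)
  if (epsilon <= 0) stopf("epsilon must be positive")
  for (eps in c(epsilon, 10 * epsilon)) {
    D <- rep(lmax + eps, p)
    X_a <- tryCatch(chol(diag(D, p) - G), error = function(e) NULL)
    if (!is.null(X_a)) {
      resid <- max(abs(G + crossprod(X_a) - diag(D, p)))
      if (resid <= 1e-8 * max(D))
        return(structure(list(X_a = X_a, D = D, epsilon = eps),
                         class = "augmented_design"))
    }
  }
  stopf("orthogonal completion failed even with inflated epsilon")
}

#' Spike-and-slab selection prior
#'
#' Independent Bernoulli(`pi`) inclusion indicators, a normal slab of
#' variance `tau2` on the standardized coefficient scale, and an intercept
#' that is always included with a vague normal prior.
#'
#' @param pi prior inclusion probability per analyte, in (0, 1).
#' @param tau2 slab variance of standardized coefficients.
#' @param intercept_var prior variance of the always-included intercept.
#' @return An object of class `selection_prior`.
#' @export
selection_prior <- function(pi = 0.5, tau2 = 1.0, intercept_var = 1e6) {
  if (pi <= 0 || pi >= 1) stopf("pi must lie strictly in (0, 1)")
  if (tau2 <= 0) stopf("tau2 must be positive")
  structure(list(pi = pi, tau2 = tau2, intercept_var = intercept_var),
            class = "selection_prior")
}

#' Conditional (Rao-Blackwell) inclusion probability
#'
#' Given the complete-data per-coordinate estimate `beta_hat_j` with
#' precision `d_j` (unit residual variance), the two marginal densities are
#' `m1 = N(beta_hat_j; 0, 1/d_j + tau2)` under inclusion and
#' `m0 = N(beta_hat_j; 0, 1/d_j)` under exclusion, and the conditional
#' inclusion probability is `pi m1 / (pi m1 + (1 - pi) m0)`. Averaging this
#' quantity over Gibbs iterations is the Rao-Blackwellized estimator of the
#' posterior inclusion probability.
#'
#' @param beta_hat least-squares estimate(s) of the coordinate.
#' @param d complete-data precision(s) `d_j > 0`.
#' @param prior a [selection_prior()].
#' @return Inclusion probabilities in `[0, 1]`, vectorized over inputs.
#' @export
conditional_inclusion_prob <- function(beta_hat, d, prior = selection_prior()) {
  if (any(!is.finite(beta_hat)) || any(!is.finite(d)) || any(d <= 0))
    stopf("beta_hat and d must be finite with d > 0")
  lm1 <- stats::dnorm(beta_hat, 0, sqrt(1 / d + prior$tau2), log = TRUE)
  lm0 <- stats::dnorm(beta_hat, 0, sqrt(1 / d), log = TRUE)
  1 / (1 + exp(log1p(-prior$pi) + lm0 - log(prior$pi) - lm1))
}

oda_posterior <- function(fit, analytes, n_iter, n_burn, seed, prior, kind) {
  rho <- stats::setNames(as.numeric(fit$rho), analytes)
  gamma <- fit$gamma
  colnames(gamma) <- analytes
  keys <- apply(gamma, 1L, paste, collapse = "")
  counts <- table(keys)
  structure(list(rho = rho, gamma_draws = gamma,
                 model_counts = stats::setNames(as.integer(counts), names(counts)),
                 beta_mean = stats::setNames(as.numeric(fit$beta_mean), analytes),
                 n_iter = n_iter, n_burn = n_burn, seed = seed,
                 prior = prior, kind = kind),
            class = "oda_posterior")
}

#' @export
print.oda_posterior <- function(x, ...) {
  cat(sprintf("<oda_posterior> %s link, %d analytes, %d post-burn draws\n",
              x$kind, length(x$rho), x$n_iter - x$n_burn))
  print(round(sort(x$rho, decreasing = TRUE), 3))
  invisible(x)
}

run_oda <- function(design, aug, prior, n_iter, n_burn, seed, probit) {
  if (!inherits(design, "design_matrix")) stopf("design must be a design_matrix")
  if (n_burn < 0 || n_iter <= n_burn) stopf("need n_iter > n_burn >= 0")
  aug <- aug %||% orthogonal_augment(design)
  y <- design$y
  if (is.null(y)) stopf("design must carry a response in $y")
  if (probit && !all(y %in% c(0, 1))) stopf("probit response must be 0/1")
  set.seed(seed)
  fit <- oda_gibbs_cpp(design$X, as.numeric(y), aug$X_a, aug$D,
                       prior$pi, prior$tau2, prior$intercept_var,
                       as.integer(n_iter), as.integer(n_burn), probit)
  oda_posterior(fit, colnames(design$X), n_iter, n_burn, seed, prior,
                if (probit) "probit" else "linear")
}

#' ODA/BMA Gibbs sampler for probit variable selection
#'
#' Bayesian model averaging over all subsets of analytes in a probit model
#' for the binary diagnosis, sampled by orthogonal data augmentation: latent
#' probit utilities are drawn truncated-normal (sign fixed by the outcome),
#' augmented responses complete the orthogonalized design, and the diagonal
#' complete-data Gram matrix renders the per-analyte inclusion indicators and
#' slab coefficients conditionally independent. Posterior inclusion
#' probabilities are Rao-Blackwellized averages of the conditional inclusion
#' probabilities over post-burn-in iterations. Deterministic given `seed`.
#'
#' @param design a [standardize_design()] result carrying the 0/1 response.
#' @param aug optional [orthogonal_augment()] result (computed if `NULL`).
#' @param prior a [selection_prior()].
#' @param n_iter total Gibbs iterations.
#' @param n_burn burn-in iterations discarded from all summaries.
#' @param seed integer seed.
#' @return An object of class `oda_posterior` with elements `rho` (named
#'   inclusion probabilities), `gamma_draws` (post-burn inclusion indicator
#'   matrix), `model_counts` (visit counts keyed by the model bitstring) and
#'   `beta_mean` (model-averaged standardized coefficients).
#' @export
run_oda_probit <- function(design, aug = NULL, prior = selection_prior(),
                           n_iter = 20000L, n_burn = 5000L, seed = 1L) {
  run_oda(design, aug, prior, n_iter, n_burn, seed, probit = TRUE)
}

#' ODA/BMA Gibbs sampler for a real-valued outcome
#'
#' Linear-outcome variant of [run_oda_probit()] without the latent-utility
#' step; the residual variance is fixed at 1, so the response should be
#' pre-scaled. Used mainly for validation against the closed-form
#' enumeration oracle.
#'
#' @inheritParams run_oda_probit
#' @return An `oda_posterior`; see [run_oda_probit()].
#' @export
run_oda_linear <- function(design, aug = NULL, prior = selection_prior(),
                           n_iter = 20000L, n_burn = 5000L, seed = 1L) {
  run_oda(design, aug, prior, n_iter, n_burn, seed, probit = FALSE)
}

#' Occam's window model pruning
#'
#' Retains the visited models whose estimated posterior probability is at
#' least `1/C` times that of the best visited model. `C = 1` keeps only the
#' top model(s); `C = Inf` keeps every visited model. A stricter (smaller)
#' window concentrates the report on the most predictive models.
#'
#' @param posterior an `oda_posterior`.
#' @param C window constant, `>= 1`.
#' @return A data frame with columns `model` (bitstring over the analytes),
#'   `count` and `prob`, sorted by probability, restricted to the window.
#' @export
occams_window <- function(posterior, C = 20) {
  if (C < 1) stopf("C must be >= 1")
  counts <- posterior$model_counts
  if (length(counts) == 0L) stopf("posterior has no visited models")
  prob <- counts / sum(counts)
  keep <- prob >= max(prob) / C
  out <- data.frame(model = names(counts)[keep],
                    count = as.integer(counts[keep]),
                    prob = as.numeric(prob[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$prob), , drop = FALSE]
}

#' Export per-analyte inclusion probabilities
#'
#' Writes the posterior inclusion probability table (and optionally the
#' visited-model list) as delimited text.
#'
#' @param posterior an `oda_posterior`.
#' @param path output path for the tab-separated rho table.
#' @param models_path optional path for the model list (bitstring, count,
#'   estimated probability).
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path, models_path = NULL) {
  df <- data.frame(analyte_id = names(posterior$rho),
                   rho = as.numeric(posterior$rho),
                   beta_mean = as.numeric(posterior$beta_mean))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(models_path)) {
    mw <- occams_window(posterior, C = Inf)
    utils::write.table(mw, models_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
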