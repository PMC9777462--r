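#' Gelman-Rubin potential scale reduction factor
#'
#' For M independently initialized chains of equal length n, the within-chain
#' variance W is the mean of the per-chain sample variances, the between-chain
#' variance is `B = n * var(chain means)`, the pooled variance estimate is
#' `V = ((n-1)/n) W + B/n`, and the statistic is `sqrt(V / W)`. Values close
#' to 1 indicate that the chains have mixed.
#'
#' @param chains a list of M numeric vectors of common length n, or an
#'   n x M numeric matrix with one chain per column.
#' @return A list with elements `rhat`, `W`, `B` and `flag`. `flag` is
#'   `"ok"` normally, `"not_converged"` when W = 0 with B > 0 (`rhat` is
#'   `Inf`), and `"degenerate_constant"` when W = B = 0 (`rhat` is `NA`).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stopf("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stopf("at least two chains are required")
  if (n < 2L) stopf("chains must have length >= 2")
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) {
    if (B > 0) return(list(rhat = Inf, W = W, B = B, flag = "not_converged"))
    return(list(rhat = NA_real_, W = W, B = B, flag = "degenerate_constant"))
  }
  V <- (n - 1) / n * W + B / n
  list(rhat = sqrt(V / W), W = W, B = B, flag = "ok")
}

## skewed strictly-positive analytes are modelled on the log scale
log_scale_analytes <- function(matrix) {
  vapply(analyte_ids(matrix), function(a) {
    obs <- matrix$values[matrix$observed[, a], a]
    length(obs) > 0L && all(obs > 0) &&
      stats::IQR(obs) > stats::median(obs)
  }, logical(1))
}

#' Initialize missing cells from empirical distributions
#'
#' Each missing cell is filled by a draw with replacement from the analyte's
#' observed values, giving every chain its own random starting point.
#'
#' @param matrix a [lab_matrix()].
#' @param seed integer seed for the draws.
#' @return A complete numeric values matrix (observed cells untouched).
#' @export
initialize_missing <- function(matrix, seed) {
  set.seed(seed)
  values <- matrix$values
  for (a in analyte_ids(matrix)) {
    obs <- values[matrix$observed[, a], a]
    if (length(obs) == 0L)
      stopf("analyte '%s' has no observed values; cannot initialize", a)
    mis <- !matrix$observed[, a]
    if (any(mis))
      values[mis, a] <- obs[sample.int(length(obs), sum(mis), replace = TRUE)]
  }
  values
}

## one posterior draw from a ridge-stabilized Bayesian linear regression
## X already contains the intercept column
bayes_lm_draw <- function(X, y, ridge_scale = 1e-6) {
  p <- ncol(X)
  A <- crossprod(X)
  lam <- ridge_scale * sum(diag(A)) / p
  R <- tryCatch(chol(A + diag(lam, p)), error = function(e) NULL)
  if (is.null(R)) {
    warnf("singular imputation design; falling back to stronger ridge")
    lam <- lam * 1e4 + 1e-8
    R <- chol(A + diag(lam, p))
  }
  Xty <- crossprod(X, y)
  betahat <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum((y - X %*% betahat)^2)
  df <- max(length(y) - p, 1L)
  sigma2 <- max(rss, 1e-12 * max(rss, 1)) / stats::rchisq(1L, df)
  beta <- betahat + sqrt(sigma2) * backsolve(R, stats::rnorm(p))
  list(beta = beta, sigma = sqrt(sigma2))
}

#' Run one chained-equation imputation chain
#'
#' After random initialization, each sweep visits the incomplete analytes in
#' descending-coverage order (ties broken by analyte id) and, for each, fits
#' a Bayesian linear regression of its observed values on all other
#' (currently completed) analytes plus the binary diagnosis label, then
#' redraws the analyte's missing cells from the posterior predictive
#' distribution. Strictly positive analytes whose IQR exceeds their median
#' are modelled on the log scale and back-transformed. Observed cells are
#' never modified.
#'
#' Near-deterministic analyte pairs (absolute working-scale correlation above
#' 0.8 on jointly observed cells, e.g. a derived eGFR and its parent
#' creatinine) would otherwise impute each other in a feedback loop whose
#' jointly missing cells random-walk along the shared curve; as in standard
#' chained-equation practice the cycle is broken by dropping the
#' later-visited analyte from the earlier-visited one's predictor set (the
#' reverse direction is kept, so the derived analyte still follows its
#' parent).
#'
#' @param matrix a [lab_matrix()] with missing cells.
#' @param labels a `cohort_labels` object or a 0/1 vector aligned to the
#'   matrix cases.
#' @param n_sweeps number of sweeps over the incomplete analytes.
#' @param collinear_r absolute correlation above which the cycle-breaking
#'   predictor exclusion applies.
#' @param seed integer seed; fixed seeds give bit-identical chains.
#' @return An object of class `imputation_chain`: the completed
#'   [lab_matrix()] in `$completed`, the per-sweep trajectory of the mean of
#'   each analyte's imputed cells (native scale) in `$trajectory`, plus the
#'   seed and the ids of the monitored (initially incomplete) analytes.
#' @export
impute_chain <- function(matrix, labels, n_sweeps = 60L, seed = 1L,
                         collinear_r = 0.8) {
  if (n_sweeps < 1L) stopf("n_sweeps must be >= 1")
  y <- if (inherits(labels, "cohort_labels"))
    labels_for(labels, case_ids(matrix)) else labels
  if (length(y) != nrow(matrix$values))
    stopf("labels do not align with the matrix cases")
  analytes <- analyte_ids(matrix)
  use_log <- log_scale_analytes(matrix)
  cov <- analyte_coverage(matrix)
  monitored <- analytes[cov < 1]
  visit <- monitored[order(-cov[monitored], monitored)]
  dropped <- collinear_exclusions(matrix, use_log, visit, collinear_r)

  work <- initialize_missing(matrix, seed)
  for (a in analytes[use_log]) work[, a] <- log(work[, a])
  trajectory <- matrix(NA_real_, n_sweeps, length(monitored),
                       dimnames = list(NULL, monitored))

  for (s in seq_len(n_sweeps)) {
    for (a in visit) {
      obs <- matrix$observed[, a]
      predictors <- setdiff(analytes, c(a, dropped[[a]]))
      X <- cbind(1, work[, predictors, drop = FALSE], label = y)
      fit <- bayes_lm_draw(X[obs, , drop = FALSE], work[obs, a])
      mu <- X[!obs, , drop = FALSE] %*% fit$beta
      work[!obs, a] <- mu + fit$sigma * stats::rnorm(sum(!obs))
    }
    for (a in monitored) {
      imp <- work[!matrix$observed[, a], a]
      trajectory[s, a] <- mean(if (use_log[[a]]) exp(imp) else imp)
    }
  }

  completed_values <- matrix$values
  for (a in analytes) {
    mis <- !matrix$observed[, a]
    if (any(mis))
      completed_values[mis, a] <- if (use_log[[a]]) exp(work[mis, a]) else work[mis, a]
  }
  completed <- lab_matrix(completed_values,
                          analyte_names = matrix$analyte_names,
                          units = matrix$units,
                          encoding_map = matrix$encoding_map)
  structure(list(completed = completed, trajectory = trajectory,
                 seed = seed, monitored = monitored,
                 log_scaled = names(use_log)[use_log],
                 collinear_dropped = dropped),
            class = "imputation_chain")
}

## one-directional predictor exclusions breaking imputation feedback loops
## between near-deterministic analyte pairs (both incomplete)
collinear_exclusions <- function(matrix, use_log, visit, r_max = 0.8) {
  dropped <- list()
  if (length(visit) < 2L) return(dropped)
  w <- matrix$values
  w[!matrix$observed] <- NA
  for (a in names(use_log)[use_log]) w[, a] <- log(w[, a])
  cm <- suppressWarnings(stats::cor(w[, visit, drop = FALSE],
                                    use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  for (i in seq_along(visit)) {
    for (j in seq_along(visit)) {
      if (i < j && abs(cm[i, j]) > r_max)
        dropped[[visit[i]]] <- c(dropped[[visit[i]]], visit[j])
    }
  }
  dropped
}

#' Multiple imputation with convergence monitoring
#'
#' Runs M independently initialized chains (seeds `base_seed + 1 .. + M`) and
#' computes the Gelman-Rubin statistic per incomplete analyte from the second
#' half of each chain's trajectory of imputed-cell means.
#'
#' @param matrix a [lab_matrix()] with missing cells.
#' @param labels labels as for [impute_chain()].
#' @param M number of chains (>= 2).
#' @param n_sweeps sweeps per chain.
#' @param base_seed integer; chain m uses seed `base_seed + m`.
#' @param rhat_threshold convergence threshold (default 1.1).
#' @return An object of class `imputed_dataset` with elements `chains` (list
#'   of `imputation_chain`), `rhat` (named vector; `NA` with a flag for
#'   complete matrices), `converged` (named logical) and `flags`.
#' @export
multiple_impute <- function(matrix, labels, M = 5L, n_sweeps = 60L,
                            base_seed = 1L, rhat_threshold = 1.1) {
  if (M < 2L) stopf("M must be >= 2 for between-chain diagnostics")
  chains <- lapply(seq_len(M), function(m) {
    tryCatch(impute_chain(matrix, labels, n_sweeps, seed = base_seed + m),
             error = function(e) stopf("chain %d failed: %s", m, conditionMessage(e)))
  })
  monitored <- chains[[1L]]$monitored
  window <- seq.int(floor(n_sweeps / 2) + 1L, n_sweeps)
  rhat <- stats::setNames(rep(NA_real_, length(monitored)), monitored)
  flags <- stats::setNames(rep("no_missing_cells", length(monitored)), monitored)
  if (length(monitored) && length(window) >= 2L) {
    for (a in monitored) {
      gr <- gelman_rubin(vapply(chains, function(ch) ch$trajectory[window, a],
                                numeric(length(window))))
      rhat[a] <- gr$rhat
      flags[a] <- gr$flag
    }
  }
  structure(list(chains = chains, rhat = rhat,
                 converged = !is.na(rhat) & rhat < rhat_threshold,
                 flags = flags, M = M, n_sweeps = n_sweeps,
                 base_seed = base_seed, rhat_threshold = rhat_threshold),
            class = "imputed_dataset")
}

#' @export
print.imputed_dataset <- function(x, ...) {
  cat(sprintf("<imputed_dataset> %d chains x %d sweeps; %d monitored analytes",
              x$M, x$n_sweeps, length(x$rhat)))
  if (length(x$rhat))
    cat(sprintf("; max R-hat %.3f (%d converged)",
                suppressWarnings(max(x$rhat, na.rm = TRUE)), sum(x$converged)))
  cat("\n")
  invisible(x)
}
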