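#' Per-analyte coverage of a laboratory matrix
#'
#' Coverage is the fraction of cases in which an analyte was measured.
#'
#' @param matrix a [lab_matrix()].
#' @return Named numeric vector in `[0, 1]`, one entry per analyte.
#' @export
analyte_coverage <- function(matrix) {
  if (nrow(matrix$values) == 0L) stopf("matrix has zero cases")
  colMeans(matrix$observed)
}

#' Restrict a matrix to a sparsity tier
#'
#' Retains exactly the analytes whose coverage is at least
#' `1 - max_missing_fraction` (boundary inclusive: the 20%-sparsity tier is
#' "measured in at least 80% of cases"). The case set is unchanged; tiers are
#' nested by construction, and an analyte with full coverage appears in every
#' tier.
#'
#' @param matrix a [lab_matrix()].
#' @param max_missing_fraction maximum allowed missingness in `[0, 1]`.
#' @return A [lab_matrix()] with the retained analytes.
#' @export
subset_by_sparsity <- function(matrix, max_missing_fraction) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stopf("max_missing_fraction must lie in [0, 1]")
  cov <- analyte_coverage(matrix)
  keep <- names(cov)[cov >= 1 - max_missing_fraction - 1e-12]
  if (length(keep) == 0L)
    stopf("no analyte satisfies coverage >= %.0f%%; nothing to model",
          100 * (1 - max_missing_fraction))
  subset_lab_matrix(matrix, analytes = keep)
}

#' Sparsity-tiered analyte subsets
#'
#' Builds the tier table: for each allowed missingness fraction, the analytes
#' retained by [subset_by_sparsity()].
#'
#' @param matrix a [lab_matrix()].
#' @param tiers numeric vector of maximum missingness fractions
#'   (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @return A list with one element per tier (named by fraction), each holding
#'   `max_missing_fraction` and `analyte_ids`.
#' @export
sparsity_tiers <- function(matrix, tiers = c(0.2, 0.4, 0.6, 0.8)) {
  tiers <- sort(tiers)
  out <- lapply(tiers, function(t)
    list(max_missing_fraction = t,
         analyte_ids = analyte_ids(subset_by_sparsity(matrix, t))))
  stats::setNames(out, format(tiers))
}
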