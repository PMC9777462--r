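#' Pool inclusion probabilities across imputation chains
#'
#' The pooled estimate is the mean over the M chain-specific inclusion
#' probabilities; uncertainty from the imputation is summarized by a normal
#' approximation interval `mean +/- 1.96 sd / sqrt(M)`, truncated to
#' `[0, 1]`. When the chains agree exactly (in particular the 100%-inclusion
#' case) or only one chain exists, no interval is reported.
#'
#' @param per_chain_rho numeric vector of M chain-specific inclusion
#'   probabilities for one analyte.
#' @return A list with `pooled`, `ci_low`, `ci_high` (both `NA` when the
#'   interval is absent) and `M`.
#' @export
pool_across_chains <- function(per_chain_rho) {
  if (length(per_chain_rho) == 0L) stopf("no chain values to pool")
  M <- length(per_chain_rho)
  pooled <- mean(per_chain_rho)
  s <- if (M >= 2L) stats::sd(per_chain_rho) else 0
  if (M >= 2L && s > 0) {
    half <- 1.96 * s / sqrt(M)
    list(pooled = pooled,
         ci_low = max(0, pooled - half),
         ci_high = min(1, pooled + half), M = M)
  } else {
    list(pooled = pooled, ci_low = NA_real_, ci_high = NA_real_, M = M)
  }
}

#' Highly predictive classification rule
#'
#' An analyte is classified highly predictive when its pooled inclusion
#' probability reaches the threshold, boundary inclusive ("95% and above").
#'
#' @param pooled_rho pooled inclusion probability in `[0, 1]` (vectorized).
#' @param threshold classification threshold, default 0.95.
#' @return Logical.
#' @export
classify_high_predictive <- function(pooled_rho, threshold = 0.95) {
  if (any(pooled_rho < 0 | pooled_rho > 1, na.rm = TRUE))
    stopf("pooled_rho must lie in [0, 1]")
  pooled_rho >= threshold
}

#' Per-tier analyte summary
#'
#' Pools each analyte's chain-specific inclusion probabilities and applies
#' the highly-predictive rule.
#'
#' @param rho_by_chain M x p matrix (chains in rows, analytes in columns) of
#'   inclusion probabilities, or a list of M named vectors.
#' @param tier the tier's maximum missingness fraction (metadata).
#' @param threshold classification threshold.
#' @return A data frame of class `analyte_summary` with one row per analyte:
#'   `analyte_id`, `tier`, `pooled_rho`, `ci_low`, `ci_high`,
#'   `high_predictive`, plus the per-chain values as an attribute.
#' @export
summarize_tier <- function(rho_by_chain, tier = NA_real_, threshold = 0.95) {
  if (is.list(rho_by_chain)) rho_by_chain <- do.call(rbind, rho_by_chain)
  pools <- apply(rho_by_chain, 2L, pool_across_chains)
  out <- data.frame(analyte_id = colnames(rho_by_chain),
                    tier = tier,
                    pooled_rho = vapply(pools, `[[`, numeric(1), "pooled"),
                    ci_low = vapply(pools, `[[`, numeric(1), "ci_low"),
                    ci_high = vapply(pools, `[[`, numeric(1), "ci_high"),
                    stringsAsFactors = FALSE)
  out$high_predictive <- classify_high_predictive(out$pooled_rho, threshold)
  rownames(out) <- NULL
  attr(out, "per_chain") <- rho_by_chain
  class(out) <- c("analyte_summary", class(out))
  out
}

#' Cross-tier report of highly predictive analytes
#'
#' Combines the per-tier summaries into the cross-tier table: one row per
#' analyte, a highly-predictive flag per tier (`NA` when the analyte is not
#' part of that tier; such tiers count as not-included in the total), and
#' the total "k of T tiers" count. Rows are sorted by total, then by mean
#' pooled inclusion probability, descending.
#'
#' @param tier_summaries named list of [summarize_tier()] results, one per
#'   tier (names are the tier fractions).
#' @return A data frame of class `cross_tier_report` with columns
#'   `analyte_id`, one logical flag column per tier (`tier_<fraction>`),
#'   `total`, `n_tiers` and `mean_rho`.
#' @export
build_report <- function(tier_summaries) {
  if (length(tier_summaries) == 0L)
    return(structure(data.frame(analyte_id = character(), total = integer(),
                                n_tiers = integer(), mean_rho = numeric()),
                     class = c("cross_tier_report", "data.frame")))
  tiers <- names(tier_summaries)
  universe <- unique(unlist(lapply(tier_summaries, `[[`, "analyte_id")))
  flags <- sapply(tier_summaries, function(s)
    s$high_predictive[match(universe, s$analyte_id)])
  flags <- matrix(flags, nrow = length(universe),
                  dimnames = list(universe, paste0("tier_", tiers)))
  rho <- sapply(tier_summaries, function(s)
    s$pooled_rho[match(universe, s$analyte_id)])
  rho <- matrix(rho, nrow = length(universe))
  out <- data.frame(analyte_id = universe, flags,
                    total = rowSums(flags, na.rm = TRUE),
                    n_tiers = length(tiers),
                    mean_rho = rowMeans(rho, na.rm = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$total, -out$mean_rho), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cross_tier_report", class(out))
  out
}

#' @export
print.cross_tier_report <- function(x, ...) {
  if (nrow(x) == 0L) { cat("<cross_tier_report> empty\n"); return(invisible(x)) }
  tier_cols <- grep("^tier_", names(x), value = TRUE)
  disp <- data.frame(analyte = x$analyte_id, stringsAsFactors = FALSE)
  for (tc in tier_cols)
    disp[[sub("tier_", "", tc)]] <-
      ifelse(is.na(x[[tc]]), "-", ifelse(x[[tc]], "+", ""))
  disp$total <- sprintf("%d/%d", x$total, x$n_tiers)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Write the cross-tier report and per-tier tables
#'
#' Emits the cross-tier table, one per-tier summary table, and per-tier
#' bar-chart data files (analyte, pooled inclusion probability, interval
#' bounds) as tab-separated text.
#'
#' @param report a [build_report()] result.
#' @param tier_summaries the per-tier summaries that fed the report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, tier_summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report), file.path(dir, "cross_tier_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "-")
  for (t in names(tier_summaries)) {
    s <- as.data.frame(tier_summaries[[t]])
    utils::write.table(s, file.path(dir, sprintf("tier_%s_summary.tsv", t)),
                       sep = "\t", row.names = FALSE, quote = FALSE, na = "")
    plot_df <- s[order(-s$pooled_rho),
                 c("analyte_id", "pooled_rho", "ci_low", "ci_high")]
    utils::write.table(plot_df, file.path(dir, sprintf("tier_%s_plotdata.tsv", t)),
                       sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(dir)
}
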