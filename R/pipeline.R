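#' Pipeline configuration
#'
#' Bundles every tunable of the full screening run: the data source (either
#' the paths of a records and a diagnoses file, or a synthetic
#' [generator_config()]), the index analyte, the ICD-10 target range, the
#' sparsity tiers, the imputation and sampler settings, the
#' highly-predictive threshold and the base seed from which every random
#' stage derives its own seed.
#'
#' @param records_path,diagnoses_path input file paths (ignored when
#'   `generator` is given).
#' @param generator optional [generator_config()] for a synthetic cohort.
#' @param troponin_id id of the index analyte whose measured cases define
#'   the cohort.
#' @param icd_range length-2 character vector of ICD-10 category bounds.
#' @param tiers maximum-missingness fractions of the sparsity tiers.
#' @param M imputation chains per tier.
#' @param n_sweeps sweeps per imputation chain.
#' @param n_iter,n_burn Gibbs iterations and burn-in per sampler run.
#' @param prior a [selection_prior()].
#' @param threshold highly-predictive classification threshold.
#' @param base_seed mandatory integer base seed.
#' @param out_dir optional output directory for report files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL, diagnoses_path = NULL,
                            generator = NULL, troponin_id = "troponin_t",
                            icd_range = c("I20", "I25"),
                            tiers = c(0.2, 0.4, 0.6, 0.8),
                            M = 5L, n_sweeps = 60L,
                            n_iter = 20000L, n_burn = 5000L,
                            prior = selection_prior(), threshold = 0.95,
                            base_seed, out_dir = NULL) {
  if (missing(base_seed)) stopf("base_seed is mandatory")
  if (is.null(generator) && (is.null(records_path) || is.null(diagnoses_path)))
    stopf("either a generator config or records + diagnoses paths are required")
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  if (M < 2L) stopf("M must be >= 2")
  structure(list(records_path = records_path, diagnoses_path = diagnoses_path,
                 generator = generator, troponin_id = troponin_id,
                 icd_range = icd_range, tiers = sort(tiers),
                 M = as.integer(M), n_sweeps = as.integer(n_sweeps),
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 prior = prior, threshold = threshold,
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analyte-screening pipeline
#'
#' Ingest (or generate) the cohort, label it, restrict it to cases with a
#' measured index analyte, and then per sparsity tier: subset the analytes,
#' run M chained-equation imputation chains with Gelman-Rubin monitoring,
#' run the ODA/BMA probit sampler once per completed dataset, and pool the
#' chain-specific inclusion probabilities into the tier summary. The
#' cross-tier report aggregates the highly-predictive flags. Every random
#' stage is seeded deterministically from `base_seed` and the (tier, chain)
#' indices, so a rerun with the same configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_result`: the `report`
#'   ([build_report()]), the per-tier `tier_summaries`, per-tier
#'   Gelman-Rubin diagnostics in `rhat`, stagewise `timings` (seconds) and
#'   the `config`. When `config$out_dir` is set the report files are also
#'   written there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  tick <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  if (!is.null(config$generator)) {
    cohort <- tick(generate_cohort(config$generator), "generate")
    masked <- tick(apply_missingness(cohort$matrix, config$generator$panel,
                                     seed = config$generator$seed + 1L,
                                     severity = cohort$truth$severity),
                   "missingness")
    labels <- cohort$labels
    matrix <- masked
  } else {
    matrix <- tick(build_lab_matrix(parse_lab_records(config$records_path)),
                   "ingest")
    labels <- tick(label_cases(read_diagnoses(config$diagnoses_path),
                               config$icd_range[1], config$icd_range[2]),
                   "label")
  }
  flt <- tick(filter_troponin_cohort(matrix, labels, config$troponin_id),
              "cohort_filter")
  matrix <- flt$matrix
  labels <- flt$labels
  say("cohort: %d cases (%d positive), %d analytes",
      nrow(matrix$values), sum(labels$labels), ncol(matrix$values))

  tier_summaries <- list()
  rhat <- list()
  for (ti in seq_along(config$tiers)) {
    tier <- config$tiers[ti]
    key <- format(tier)
    sub <- tick(subset_by_sparsity(matrix, tier), paste0("subset_", key))
    say("tier %s: %d analytes", key, ncol(sub$values))
    imp <- tick(multiple_impute(sub, labels, M = config$M,
                                n_sweeps = config$n_sweeps,
                                base_seed = derive_seed(config$base_seed, ti, 0L)),
                paste0("impute_", key))
    if (length(imp$rhat))
      say("tier %s: max R-hat %.3f (%d/%d converged)", key,
          suppressWarnings(max(imp$rhat, na.rm = TRUE)),
          sum(imp$converged), length(imp$rhat))
    y <- labels_for(labels, case_ids(sub))
    rho <- tick(t(vapply(seq_len(config$M), function(m) {
      des <- standardize_design(imp$chains[[m]]$completed$values, y = y)
      post <- run_oda_probit(des, prior = config$prior,
                             n_iter = config$n_iter, n_burn = config$n_burn,
                             seed = derive_seed(config$base_seed, ti, m))
      post$rho
    }, numeric(ncol(sub$values)))), paste0("sampler_", key))
    tier_summaries[[key]] <- summarize_tier(rho, tier = tier,
                                            threshold = config$threshold)
    rhat[[key]] <- imp$rhat
    nhp <- sum(tier_summaries[[key]]$high_predictive)
    say("tier %s: %d highly predictive analyte(s)", key, nhp)
  }

  report <- build_report(tier_summaries)
  if (!is.null(config$out_dir)) {
    write_report(report, tier_summaries, config$out_dir)
    rh <- data.frame(tier = rep(names(rhat), lengths(rhat)),
                     analyte_id = unlist(lapply(rhat, names)),
                     rhat = unlist(rhat, use.names = FALSE))
    utils::write.table(rh, file.path(config$out_dir, "gelman_rubin.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(report = report, tier_summaries = tier_summaries,
                 rhat = rhat, timings = unlist(timings), config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
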