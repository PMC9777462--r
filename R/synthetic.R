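#' CKD-EPI estimated glomerular filtration rate
#'
#' Computes eGFR (mL/min/1.73 m^2) from serum creatinine, age and sex by the
#' CKD-EPI equation:
#' `141 * min(Scr/kappa, 1)^a * max(Scr/kappa, 1)^(-1.209) * 0.993^Age
#'  * 1.018 (if female) * 1.159 (if black)`,
#' with `kappa = 0.7` (female) / `0.9` (male) and `a = -0.329` (female) /
#' `-0.411` (male). All arguments are vectorized.
#'
#' @param scr serum creatinine in mg/dL (must be positive).
#' @param age age in years (non-negative).
#' @param female logical.
#' @param black logical; the race factor of the legacy equation, default
#'   `FALSE`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckdepi_egfr <- function(scr, age, female, black = FALSE) {
  if (any(scr <= 0)) stopf("serum creatinine must be positive")
  if (any(age < 0)) stopf("age must be non-negative")
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^a * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Default synthetic analyte panel
#'
#' One row per analyte: distribution family (`lognormal`, `normal`,
#' `binary`), native-unit median and IQR targets taken from routine
#' emergency-laboratory values, the standardized probit coefficient on the
#' latent scale (0 for null analytes; the troponin analog dominates), a
#' coverage target with its missingness mechanism (`MCAR` or
#' `MAR_on_severity`), and the loading on the shared latent severity factor
#' that induces correlation among analytes. The eGFR row is derived from
#' creatinine, age and sex via [ckdepi_egfr()] rather than drawn. Coverage
#' targets are spread over the four sparsity bands so that tiering the
#' cohort reproduces the nested-subset structure of the analysis.
#'
#' @param dominant_coef standardized probit coefficient of the fully
#'   observed troponin analog (default 2).
#' @return A data frame of analyte specifications.
#' @export
default_analyte_panel <- function(dominant_coef = 2.0) {
  spec <- function(id, name, family, median, iqr, unit, coef = 0,
                   coverage = 1, miss = "MCAR", loading = 0.3,
                   derived_from = NA_character_, binary_p = NA_real_)
    data.frame(analyte_id = id, name = name, family = family,
               median = median, iqr = iqr, unit = unit, coef = coef,
               coverage = coverage, missingness = miss, loading = loading,
               derived_from = derived_from, binary_p = binary_p,
               stringsAsFactors = FALSE)
  rbind(
    ## coverage >= 0.8 band: the routinely measured panel
    spec("troponin_t", "Troponin T", "lognormal", 20, 43.02, "ng/L",
         coef = dominant_coef, coverage = 1.0, loading = 0.6),
    spec("potassium", "Potassium", "normal", 4.0, 0.5, "mmol/L",
         coef = 0.8, coverage = 0.95, loading = 0.35),
    spec("sodium", "Sodium", "normal", 140, 6, "mmol/L",
         coverage = 0.93, loading = 0.2),
    spec("glucose", "Glucose", "lognormal", 5.96, 2.11, "mmol/L",
         coverage = 0.9, loading = 0.3),
    spec("creatinine", "Creatinine", "lognormal", 0.9, 0.4, "mg/dL",
         coverage = 0.88, loading = 0.4),
    spec("creatine_kinase", "Creatine kinase", "lognormal", 96, 126, "U/L",
         coverage = 0.85, loading = 0.3),
    spec("egfr", "eGFR (CKD-EPI)", "lognormal", 84, 39, "mL/min/1.73m2",
         derived_from = "creatinine"),
    spec("hemoglobin", "Hemoglobin", "normal", 138, 22, "g/L",
         coverage = 0.82, loading = 0.25),
    ## 0.6 - 0.8 band
    spec("urea", "Urea", "lognormal", 5.9, 4.4, "mmol/L",
         coef = 0.5, coverage = 0.75, miss = "MAR_on_severity", loading = 0.5),
    spec("rdw", "Red cell distribution width", "normal", 13.5, 1.9, "%",
         coverage = 0.72, loading = 0.2),
    spec("inr", "INR", "lognormal", 1.1, 0.13, "",
         coverage = 0.7, miss = "MAR_on_severity", loading = 0.3),
    spec("collection_type", "Type of blood collection", "binary", NA, NA, "",
         coverage = 0.68, loading = 0.45, binary_p = 0.25),
    spec("mcv", "MCV", "normal", 86, 7, "fl", coverage = 0.66, loading = 0.1),
    spec("mch", "MCH", "normal", 30, 3, "pg", coverage = 0.63, loading = 0.1),
    spec("mchc", "MCHC", "normal", 343, 17, "g/L",
         coverage = 0.61, loading = 0.1),
    ## 0.4 - 0.6 band
    spec("thrombin_time", "Thrombin time", "lognormal", 16, 2.5, "s",
         coverage = 0.55, loading = 0.25),
    spec("ck_mb_mass", "CK-MB mass", "lognormal", 4.6, 11.5, "ug/L",
         coverage = 0.52, miss = "MAR_on_severity", loading = 0.45),
    spec("calcium_total", "Calcium total", "normal", 2.24, 0.2, "mmol/L",
         coverage = 0.5, loading = 0.2),
    spec("chloride", "Chloride", "normal", 107, 7, "mmol/L",
         coverage = 0.46, loading = 0.2),
    spec("bilirubin", "Bilirubin", "lognormal", 8, 10, "umol/L",
         coverage = 0.42, loading = 0.3),
    ## 0.2 - 0.4 band
    spec("hdl_cholesterol", "HDL cholesterol", "lognormal", 1.23, 0.55,
         "mmol/L", coverage = 0.38, loading = 0.15),
    spec("ldl_cholesterol", "LDL cholesterol", "lognormal", 2.25, 1.38,
         "mmol/L", coverage = 0.35, loading = 0.15),
    spec("fio2", "FiO2", "lognormal", 32, 43, "mmHg",
         coverage = 0.32, miss = "MAR_on_severity", loading = 0.4),
    spec("crp", "C-reactive protein", "lognormal", 5, 12, "mg/L",
         coverage = 0.3, loading = 0.35),
    spec("lactate", "Lactate", "lognormal", 1.8, 1.1, "mmol/L",
         coverage = 0.28, miss = "MAR_on_severity", loading = 0.4),
    spec("albumin", "Albumin", "normal", 38, 7, "g/L",
         coverage = 0.25, loading = 0.25),
    spec("lipase", "Lipase", "lognormal", 40, 35, "U/L",
         coverage = 0.22, loading = 0.1),
    spec("tsh", "TSH", "lognormal", 1.8, 1.6, "mU/L",
         coverage = 0.2, loading = 0.1)
  )
}

#' Minimal analyte panel for recovery experiments
#'
#' A bare panel of `p` standard-normal analytes: analyte 1 plays the fully
#' observed troponin-analog role, the first `length(true_coef)` analytes
#' carry the given standardized probit coefficients, and all others are null
#' with uniform MCAR coverage.
#'
#' @param p number of analytes.
#' @param true_coef standardized probit coefficients of the leading analytes.
#' @param coverage MCAR coverage target of analytes 2..p.
#' @param loading shared-severity loading of every analyte.
#' @return A panel data frame as in [default_analyte_panel()].
#' @export
simple_panel <- function(p = 20L, true_coef = c(1.0, 0.8, 0.5),
                         coverage = 0.7, loading = 0.3) {
  coef <- c(true_coef, rep(0, p - length(true_coef)))
  data.frame(analyte_id = sprintf("a%02d", seq_len(p)),
             name = sprintf("analyte %02d", seq_len(p)),
             family = "normal", median = 0, iqr = 2 * stats::qnorm(0.75),
             unit = "", coef = coef,
             coverage = c(1, rep(coverage, p - 1L)),
             missingness = "MCAR", loading = loading,
             derived_from = NA_character_, binary_p = NA_real_,
             stringsAsFactors = FALSE)
}

#' Synthetic cohort generator configuration
#'
#' @param n_cases number of cases.
#' @param prevalence target marginal prevalence of the diagnosis, in (0, 1).
#' @param panel analyte panel (default [default_analyte_panel()]).
#' @param seed mandatory integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases = 2000L, prevalence = 0.1,
                             panel = default_analyte_panel(), seed) {
  if (missing(seed)) stopf("a seed is mandatory for the generator")
  if (prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must lie strictly in (0, 1)")
  if (any(panel$coef != 0 & !is.na(panel$derived_from)))
    stopf("derived analytes cannot carry a direct coefficient")
  ln <- panel$family == "lognormal" & is.na(panel$derived_from)
  if (any(ln & panel$median <= 0))
    stopf("lognormal analytes need a positive median target")
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 panel = panel, seed = as.integer(seed)),
            class = "generator_config")
}

lognormal_sigma <- function(median, iqr) asinh(iqr / (2 * median)) / stats::qnorm(0.75)

#' Generate a complete synthetic laboratory cohort
#'
#' Draws a shared latent severity factor per case, per-analyte latent
#' standard normals correlated through their severity loadings, and native
#' values by family: lognormal analytes are calibrated so that the sample
#' median and IQR approach the panel targets (log-median `log(m)`, log-sd
#' solved from the IQR/median ratio), normal analytes use
#' `median + IQR/1.349 * z`, and binary analytes threshold the latent normal
#' at their marginal rate. The median targets are anchored at the control
#' stratum (clinical reference tables report the non-diseased medians;
#' predictive analytes are shifted upward in cases), so the location is
#' centred on the control cases' latent median. The binary diagnosis follows a probit link on the
#' standardized latents of the true-predictor analytes, with the intercept
#' solved numerically for the prevalence target. Derived analytes (eGFR) are
#' computed deterministically from their parents plus per-case age and sex.
#' ICD-10-style diagnosis code lists are synthesized consistently with the
#' labels (in-range codes for cases, out-of-range for controls).
#'
#' @param config a [generator_config()].
#' @return A list with `matrix` (complete [lab_matrix()]), `labels`
#'   (`cohort_labels`), `diagnoses` (named list of ICD-10 codes) and `truth`
#'   (coefficients, intercept, latent severity and analyte scores, age, sex).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_cases
  panel <- config$panel
  cases <- sprintf("case%05d", seq_len(n))
  severity <- stats::rnorm(n)
  drawn <- panel[is.na(panel$derived_from), , drop = FALSE]

  z <- sapply(seq_len(nrow(drawn)), function(j) {
    l <- drawn$loading[j]
    l * severity + sqrt(1 - l^2) * stats::rnorm(n)
  })
  colnames(z) <- drawn$analyte_id

  ## diagnosis through a probit link on the standardized latent scores
  eta0 <- as.numeric(z %*% drawn$coef)
  a0 <- tryCatch(
    stats::uniroot(function(a) mean(stats::pnorm(a + eta0)) - config$prevalence,
                   c(-35, 35), tol = 1e-10)$root,
    error = function(e) stopf("prevalence target %.3f is unreachable",
                              config$prevalence))
  y <- stats::rbinom(n, 1L, stats::pnorm(a0 + eta0))

  ## native values; the median/IQR targets describe the control stratum
  ## (predictive analytes are shifted in cases), so location is anchored at
  ## the control-stratum latent median
  values <- matrix(NA_real_, n, nrow(panel),
                   dimnames = list(cases, panel$analyte_id))
  encoding_map <- list()
  for (j in seq_len(nrow(drawn))) {
    id <- drawn$analyte_id[j]
    zc <- z[, id] - stats::median(z[y == 0L, id])
    values[, id] <- switch(drawn$family[j],
      lognormal = exp(log(drawn$median[j]) +
                        lognormal_sigma(drawn$median[j], drawn$iqr[j]) * zc),
      normal = drawn$median[j] + drawn$iqr[j] / (2 * stats::qnorm(0.75)) * zc,
      binary = as.numeric(z[, id] > stats::qnorm(1 - drawn$binary_p[j])),
      stopf("unknown family '%s'", drawn$family[j]))
    if (drawn$family[j] == "binary")
      encoding_map[[id]] <- c(arterial = 1, venous = 0)
  }

  ## demographics and derived analytes
  age <- pmin(pmax(round(stats::rnorm(n, 65, 16)), 18), 99)
  female <- stats::runif(n) < 0.45
  for (j in which(!is.na(panel$derived_from))) {
    parent <- panel$derived_from[j]
    if (!parent %in% colnames(values)) stopf("derived parent '%s' missing", parent)
    values[, panel$analyte_id[j]] <- ckdepi_egfr(values[, parent], age, female)
  }

  mi_codes <- c("I20.0", "I21.4", "I21.9", "I22.1", "I24.8", "I25.1", "I25.90")
  other_codes <- c("J18.9", "K52.9", "E11.9", "N39.0", "M54.5", "R07.4", "I10")
  diagnoses <- lapply(seq_len(n), function(i) {
    extra <- sample(other_codes, sample(0:2, 1))
    if (y[i] == 1L) c(sample(mi_codes, 1), extra)
    else if (length(extra)) extra else sample(other_codes, 1)
  })
  names(diagnoses) <- cases

  m <- lab_matrix(values, analyte_names = panel$name,
                  units = panel$unit, encoding_map = encoding_map)
  labels <- structure(list(labels = stats::setNames(y, cases),
                           target_range = c("I20", "I25")),
                      class = "cohort_labels")
  truth <- list(coefficients = stats::setNames(panel$coef, panel$analyte_id),
                intercept = a0, severity = severity, latent = z,
                age = age, female = female,
                prevalence_realized = mean(y), seed = config$seed)
  list(matrix = m, labels = labels, diagnoses = diagnoses, truth = truth)
}

#' Hide cells according to the panel's coverage targets
#'
#' MCAR analytes hide each cell independently at rate `1 - coverage`;
#' `MAR_on_severity` analytes hide with probability logistic in the latent
#' severity (unit slope), the intercept solved so that the marginal hiding
#' rate matches the coverage target. Fully covered analytes - in particular
#' the troponin analog - are never hidden; derived analytes inherit their
#' parent's mask.
#'
#' @param complete a complete [lab_matrix()] from [generate_cohort()].
#' @param panel the analyte panel used to generate it.
#' @param seed integer seed for the hiding draws.
#' @param severity latent severity vector (`truth$severity`); required when
#'   any analyte uses `MAR_on_severity`.
#' @return A [lab_matrix()] with missing cells.
#' @export
apply_missingness <- function(complete, panel, seed, severity = NULL) {
  set.seed(seed)
  values <- complete$values
  n <- nrow(values)
  for (j in seq_len(nrow(panel))) {
    if (!is.na(panel$derived_from[j])) next
    rate <- 1 - panel$coverage[j]
    if (rate <= 0) next
    id <- panel$analyte_id[j]
    if (panel$missingness[j] == "MAR_on_severity") {
      if (is.null(severity)) stopf("MAR_on_severity requires the severity vector")
      a <- stats::uniroot(function(a) mean(stats::plogis(a + severity)) - rate,
                          c(-35, 35), tol = 1e-10)$root
      hide <- stats::runif(n) < stats::plogis(a + severity)
    } else {
      hide <- stats::runif(n) < rate
    }
    values[hide, id] <- NA
  }
  for (j in which(!is.na(panel$derived_from)))
    values[is.na(values[, panel$derived_from[j]]), panel$analyte_id[j]] <- NA
  lab_matrix(values, analyte_names = complete$analyte_names,
             units = complete$units, encoding_map = complete$encoding_map)
}

#' Write a synthetic cohort as the raw text files the pipeline ingests
#'
#' Emits the long-format records file (one observed measurement per row,
#' categorical analytes as their tokens), the diagnoses file
#' (semicolon-separated ICD-10 codes) and a truth file (analyte, true
#' standardized coefficient), so that a generated cohort can be round-tripped
#' through [parse_lab_records()] and [build_lab_matrix()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param matrix optionally a masked matrix from [apply_missingness()] to
#'   write instead of the complete one.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort_files <- function(cohort, dir, matrix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- matrix %||% cohort$matrix
  obs <- which(m$observed, arr.ind = TRUE)
  ids <- analyte_ids(m)[obs[, 2L]]
  vals <- as.character(m$values[obs])
  for (a in names(m$encoding_map)) {
    codes <- m$encoding_map[[a]]
    sel <- ids == a
    vals[sel] <- names(codes)[match(m$values[obs][sel], codes)]
  }
  rec <- data.frame(case_id = case_ids(m)[obs[, 1L]],
                    analyte_id = ids,
                    analyte_name = unname(m$analyte_names[ids]),
                    value = vals,
                    unit = unname(m$units[ids]),
                    timestamp = 1,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$case_id, rec$analyte_id), , drop = FALSE]
  records_path <- file.path(dir, "lab_records.csv")
  utils::write.table(rec, records_path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  diag_path <- file.path(dir, "diagnoses.csv")
  utils::write.table(
    data.frame(case_id = names(cohort$diagnoses),
               codes = vapply(cohort$diagnoses, paste, "", collapse = ";")),
    diag_path, sep = ",", row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(analyte_id = names(cohort$truth$coefficients),
               true_coefficient = cohort$truth$coefficients),
    truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(records = records_path, diagnoses = diag_path, truth = truth_path))
}
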