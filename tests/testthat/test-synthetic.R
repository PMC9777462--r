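test_that("CKD-EPI eGFR matches direct evaluation of the equation", {
  ## both power terms equal 1: female at Scr = kappa, age 0
  expect_equal(ckdepi_egfr(0.7, 0, female = TRUE), 141 * 1.018)
  ## male at Scr = kappa = 0.9, age 60
  expect_equal(ckdepi_egfr(0.9, 60, female = FALSE), 141 * 0.993^60)
  expect_equal(round(ckdepi_egfr(0.9, 60, female = FALSE), 1), 92.5)
  ## the published worked example (female, 53 y, Scr 0.8): the formula gives
  ## ~84.2, not the 88 printed alongside it
  direct <- 141 * min(0.8 / 0.7, 1)^(-0.329) * max(0.8 / 0.7, 1)^(-1.209) *
    0.993^53 * 1.018
  expect_equal(ckdepi_egfr(0.8, 53, female = TRUE), direct, tolerance = 1e-12)
  expect_equal(round(direct, 1), 84.2)
  ## grid agreement against an independent inline evaluation
  grid <- expand.grid(scr = c(0.5, 0.8, 1.1, 2.5), age = c(20, 53, 87),
                      female = c(TRUE, FALSE), black = c(TRUE, FALSE))
  got <- with(grid, ckdepi_egfr(scr, age, female, black))
  ref <- apply(grid, 1L, function(r) {
    scr <- as.numeric(r[["scr"]]); age <- as.numeric(r[["age"]])
    fem <- as.logical(r[["female"]]); blk <- as.logical(r[["black"]])
    kap <- if (fem) 0.7 else 0.9
    a <- if (fem) -0.329 else -0.411
    141 * min(scr / kap, 1)^a * max(scr / kap, 1)^(-1.209) * 0.993^age *
      (if (fem) 1.018 else 1) * (if (blk) 1.159 else 1)
  })
  expect_equal(got, ref, tolerance = 1e-10)
  expect_error(ckdepi_egfr(-1, 50, TRUE), "positive")
})

test_that("the generator hits its distributional targets", {
  cfg <- generator_config(n_cases = 5000, prevalence = 0.1, seed = 41)
  cohort <- generate_cohort(cfg)
  v <- cohort$matrix$values
  y <- cohort$labels$labels
  ## troponin analog: control-stratum median within 10% of the 20 ng/L target
  expect_lt(abs(median(v[y == 0, "troponin_t"]) / 20 - 1), 0.10)
  ## a null lognormal analyte matches median and IQR targets
  expect_lt(abs(median(v[, "glucose"]) / 5.96 - 1), 0.10)
  expect_lt(abs(IQR(v[, "glucose"]) / 2.11 - 1), 0.15)
  ## prevalence close to target
  expect_lt(abs(mean(y) - 0.1), 0.02)
  ## determinism
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$matrix$values, cohort2$matrix$values)
  expect_identical(cohort$labels$labels, cohort2$labels$labels)
  ## derived eGFR recomputes bitwise from its parents
  tr <- cohort$truth
  expect_identical(v[, "egfr"],
                   ckdepi_egfr(v[, "creatinine"], tr$age, tr$female))
})

test_that("null generators produce labels independent of the analytes", {
  panel <- simple_panel(p = 5L, true_coef = numeric(0), coverage = 1)
  hits <- 0L
  for (s in 1:20) {
    cohort <- generate_cohort(generator_config(n_cases = 400, prevalence = 0.3,
                                               panel = panel, seed = 100 + s))
    pv <- suppressWarnings(
      chisq.test(table(cohort$matrix$values[, "a01"] > 0,
                       cohort$labels$labels))$p.value)
    if (pv > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("missingness honours coverage targets and mechanisms", {
  panel <- default_analyte_panel()
  cfg <- generator_config(n_cases = 10000, prevalence = 0.1, seed = 51)
  cohort <- generate_cohort(cfg)
  masked <- apply_missingness(cohort$matrix, panel, seed = 52,
                              severity = cohort$truth$severity)
  cov <- analyte_coverage(masked)
  ## troponin analog is never hidden
  expect_identical(cov[["troponin_t"]], 1.0)
  ## MCAR analyte at its binomial rate
  expect_gt(cov[["inr"]], 0.68); expect_lt(cov[["inr"]], 0.72)
  expect_gt(cov[["glucose"]], 0.88); expect_lt(cov[["glucose"]], 0.92)
  ## full-coverage target hides nothing
  expect_identical(masked$values[, "troponin_t"],
                   cohort$matrix$values[, "troponin_t"])
  ## derived analyte inherits its parent's mask
  expect_identical(is.na(masked$values[, "egfr"]),
                   is.na(masked$values[, "creatinine"]))
  ## MAR mechanism: hidden and observed severities differ detectably...
  s <- cohort$truth$severity
  hidden <- is.na(masked$values[, "urea"])
  expect_lt(ks.test(s[hidden], s[!hidden])$p.value, 1e-6)
  ## ...while an MCAR analyte shows no such shift
  hidden_mcar <- is.na(masked$values[, "chloride"])
  expect_gt(ks.test(s[hidden_mcar], s[!hidden_mcar])$p.value, 0.01)
})

test_that("generated cohorts round-trip through the records reader", {
  cohort <- generate_cohort(generator_config(n_cases = 60, prevalence = 0.2,
                                             seed = 61))
  masked <- apply_missingness(cohort$matrix, default_analyte_panel(),
                              seed = 62, severity = cohort$truth$severity)
  dir <- withr::local_tempdir()
  paths <- write_cohort_files(cohort, dir, matrix = masked)
  rec <- parse_lab_records(paths[["records"]])
  m <- build_lab_matrix(rec)
  cases <- rownames(masked$values)
  expect_setequal(rownames(m$values), cases)
  expect_setequal(colnames(m$values), colnames(masked$values))
  expect_equal(m$values[cases, colnames(masked$values)], masked$values,
               tolerance = 1e-9)
  expect_equal(m$encoding_map$collection_type,
               masked$encoding_map$collection_type)
  ## labels recomputed from the written diagnoses match the generator's
  lb <- label_cases(read_diagnoses(paths[["diagnoses"]]))
  expect_equal(labels_for(lb, cases), cohort$labels$labels[cases])
})

test_that("unreachable prevalence and invalid panels are rejected", {
  expect_error(generator_config(n_cases = 100, prevalence = 1.2, seed = 1),
               "prevalence")
  bad <- default_analyte_panel()
  bad$coef[bad$analyte_id == "egfr"] <- 1
  expect_error(generator_config(panel = bad, seed = 1), "derived")
})
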