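test_that("Gelman-Rubin statistic matches its closed form and flags degeneracies", {
  ## two identical chains of [1,2,3,4]: W = 5/3, B = 0, rhat = sqrt(3/4)
  gr <- gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(gr$W, 5 / 3)
  expect_equal(gr$B, 0)
  expect_equal(gr$rhat, sqrt(3 / 4))
  ## identical chains at any length n give sqrt((n-1)/n)
  for (n in c(2L, 7L, 50L)) {
    x <- rnorm(n)
    expect_equal(gelman_rubin(list(x, x, x))$rhat, sqrt((n - 1) / n))
  }
  ## divergent constant chains: W = 0, B > 0 -> infinite, flagged
  gr2 <- gelman_rubin(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_identical(gr2$rhat, Inf)
  expect_equal(gr2$flag, "not_converged")
  ## all-constant chains are degenerate
  gr3 <- gelman_rubin(list(c(2, 2, 2), c(2, 2, 2)))
  expect_true(is.na(gr3$rhat))
  expect_equal(gr3$flag, "degenerate_constant")
  expect_error(gelman_rubin(list(1:3)), "two chains")
})

test_that("same-distribution chains drive the statistic towards 1", {
  set.seed(1)
  rhats <- sapply(c(20L, 2000L), function(n)
    gelman_rubin(lapply(1:4, function(i) rnorm(n)))$rhat)
  expect_lt(abs(rhats[2] - 1), abs(rhats[1] - 1) + 0.02)
  expect_lt(rhats[2], 1.01)
})

test_that("initialization draws from each analyte's empirical support", {
  v <- matrix(c(5, NA, NA, 1, 2, 3), 3,
              dimnames = list(c("c1","c2","c3"), c("a", "b")))
  m <- lab_matrix(v)
  filled <- initialize_missing(m, seed = 3)
  ## single-support analyte imputes its only observed value
  expect_equal(unname(filled[c("c2", "c3"), "a"]), c(5, 5))
  expect_equal(filled[, "b"], v[, "b"])
  ## determinism under the seed
  expect_identical(filled, initialize_missing(m, seed = 3))
  ## complete matrix is untouched
  mc <- lab_matrix(matrix(1:4 * 1.0, 2, dimnames = list(c("x","y"), c("a","b"))))
  expect_identical(initialize_missing(mc, 1), mc$values)
  ## empty analyte support is an error naming the analyte
  m2 <- lab_matrix(matrix(c(NA, NA, 1, 2), 2,
                          dimnames = list(c("c1","c2"), c("bad", "ok"))))
  expect_error(initialize_missing(m2, 1), "bad")
})

test_that("chained imputation recovers an exact linear dependency", {
  set.seed(7)
  n <- 200L
  b <- rnorm(n, 10, 3)
  a <- 2 * b
  a[1:5] <- NA
  m <- toy_lab_matrix(cbind(a = a, b = b))
  y <- rep(0L, n)
  ch <- impute_chain(m, y, n_sweeps = 20, seed = 2)
  imputed <- ch$completed$values[1:5, "a"]
  ## with a = 2b exactly, the residual noise is tiny
  expect_lt(max(abs(imputed - 2 * b[1:5])), 0.5)
  ## observed cells bitwise untouched
  expect_identical(unname(ch$completed$values[-(1:5), "a"]), a[-(1:5)])
  expect_identical(unname(ch$completed$values[, "b"]), b)
  ## determinism / seed sensitivity
  ch2 <- impute_chain(m, y, n_sweeps = 20, seed = 2)
  expect_identical(ch$completed$values, ch2$completed$values)
  ch3 <- impute_chain(m, y, n_sweeps = 20, seed = 3)
  expect_false(identical(ch$completed$values, ch3$completed$values))
})

test_that("a complete matrix passes through unchanged with flat trajectory", {
  set.seed(8)
  m <- toy_lab_matrix(matrix(rnorm(40, 50, 5), 10))
  ch <- impute_chain(m, rep(0L, 10), n_sweeps = 5, seed = 1)
  expect_identical(ch$completed$values, m$values)
  expect_equal(ncol(ch$trajectory), 0L)
})

test_that("multiple imputation produces converged, seed-stable chains", {
  set.seed(21)
  n <- 300L
  z <- rnorm(n)
  v <- cbind(a = 50 + 5 * z + rnorm(n),
             b = 20 + 3 * z + rnorm(n),
             c = 10 - 2 * z + rnorm(n))
  v[sample(n, 90), "b"] <- NA
  v[sample(n, 60), "c"] <- NA
  m <- toy_lab_matrix(v)
  y <- as.integer(runif(n) < 0.2)
  imp <- multiple_impute(m, y, M = 3, n_sweeps = 30, base_seed = 5)
  expect_length(imp$chains, 3L)
  expect_equal(sort(names(imp$rhat)), c("b", "c"))
  expect_true(all(imp$rhat < 1.2))
  ## chains differ between seeds but reruns are identical
  imp2 <- multiple_impute(m, y, M = 3, n_sweeps = 30, base_seed = 5)
  expect_identical(imp$chains[[2]]$completed$values,
                   imp2$chains[[2]]$completed$values)
  expect_false(identical(imp$chains[[1]]$completed$values,
                         imp$chains[[2]]$completed$values))
  expect_error(multiple_impute(m, y, M = 1), "M must be")
})

test_that("convergence improves with sweep count on synthetic data", {
  cohort <- generate_cohort(generator_config(n_cases = 600, prevalence = 0.1,
                                             seed = 47))
  masked <- apply_missingness(cohort$matrix, default_analyte_panel(),
                              seed = 48, severity = cohort$truth$severity)
  sub <- subset_by_sparsity(masked, 0.6)
  imp <- multiple_impute(sub, cohort$labels, M = 4, n_sweeps = 40,
                         base_seed = 9)
  rhat_window <- function(w) sapply(imp$chains[[1]]$monitored, function(a)
    gelman_rubin(sapply(imp$chains, function(ch) ch$trajectory[w, a]))$rhat)
  early <- rhat_window(2:11)
  late <- rhat_window(31:40)
  ## the early window includes the initialization transient
  expect_lt(mean(late), mean(early) + 0.05)
  expect_lt(max(imp$rhat), 1.2)
})

test_that("imputation honours the missing-at-random structure on synthetic data", {
  ## the imputed-cell means stay near the truth for a MAR analyte
  cohort <- generate_cohort(generator_config(n_cases = 1200, prevalence = 0.1,
                                             seed = 31))
  panel <- default_analyte_panel()
  masked <- apply_missingness(cohort$matrix, panel, seed = 32,
                              severity = cohort$truth$severity)
  sub <- subset_by_sparsity(masked, 0.4)
  ch <- impute_chain(sub, cohort$labels, n_sweeps = 15, seed = 4)
  for (a in ch$monitored) {
    truth_mean <- mean(cohort$matrix$values[!masked$observed[, a], a])
    imput_mean <- mean(ch$completed$values[!masked$observed[, a], a])
    scale_ref <- sd(cohort$matrix$values[, a])
    expect_lt(abs(imput_mean - truth_mean) / scale_ref, 0.6)
  }
})
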