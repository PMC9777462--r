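## small in-code fixtures shared across test files

write_records_fixture <- function(path, sep = ",") {
  lines <- c(
    paste("case_id", "analyte_id", "analyte_name", "value", "unit",
          "timestamp", sep = sep),
    paste("c1", "tnt", "Troponin T", "12.5", "ng/L", "1", sep = sep),
    paste("c1", "k", "Potassium", "4.1", "mmol/L", "1", sep = sep),
    paste("c2", "tnt", "Troponin T", "250", "ng/L", "2", sep = sep))
  writeLines(lines, path)
  path
}

toy_lab_matrix <- function(values, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("a%d", seq_len(ncol(values)))
  lab_matrix(values, ...)
}

## a random linear-model instance for oracle comparisons
random_linear_instance <- function(seed, n = 300L, p_max = 10L) {
  set.seed(seed)
  p <- sample(2:p_max, 1L)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("v%02d", 1:p)))
  n_true <- sample(0:min(3L, p), 1L)
  b <- numeric(p)
  if (n_true > 0)
    b[sample(p, n_true)] <- runif(n_true, 0.2, 0.8) * sample(c(-1, 1), n_true, TRUE)
  y <- as.numeric(x %*% b + rnorm(n))
  standardize_design(x, y = y)
}
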