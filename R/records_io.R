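#' Construct a case-by-analyte laboratory matrix
#'
#' The central container of the package: a numeric cases x analytes matrix in
#' which `NA` marks a measurement that was never requested, together with the
#' explicit observation mask, per-analyte display names and units, and the
#' numeric encodings used for categorical analytes (e.g. type of blood
#' collection).
#'
#' @param values numeric matrix, cases in rows and analytes in columns, with
#'   `NA` in unobserved cells; must have row and column names.
#' @param analyte_names optional character vector of display names (defaults
#'   to the column names).
#' @param units optional character vector of measurement units per analyte.
#' @param encoding_map named list mapping a categorical analyte id to a named
#'   numeric vector `c(token = code, ...)`.
#' @return An object of class `lab_matrix`.
#' @export
lab_matrix <- function(values, analyte_names = NULL, units = NULL,
                       encoding_map = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(colnames(values)))
    stopf("`values` must carry analyte ids as colnames")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L)
      stopf("`values` must carry case ids as rownames")
    rownames(values) <- character(0)
  }
  if (anyDuplicated(colnames(values)))
    stopf("analyte ids must be unique")
  if (any(!is.finite(values) & !is.na(values)))
    stopf("observed cells must be finite")
  analyte_names <- analyte_names %||% colnames(values)
  units <- units %||% rep(NA_character_, ncol(values))
  structure(list(values = values,
                 observed = !is.na(values),
                 analyte_names = stats::setNames(analyte_names, colnames(values)),
                 units = stats::setNames(units, colnames(values)),
                 encoding_map = encoding_map),
            class = "lab_matrix")
}

#' @export
print.lab_matrix <- function(x, ...) {
  cat(sprintf("<lab_matrix> %d cases x %d analytes, %.1f%% observed\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  invisible(x)
}

#' @export
dim.lab_matrix <- function(x) dim(x$values)

case_ids <- function(m) rownames(m$values)
analyte_ids <- function(m) colnames(m$values)

subset_lab_matrix <- function(m, cases = NULL, analytes = NULL) {
  cases <- cases %||% case_ids(m)
  analytes <- analytes %||% analyte_ids(m)
  lab_matrix(m$values[cases, analytes, drop = FALSE],
             analyte_names = m$analyte_names[analytes],
             units = m$units[analytes],
             encoding_map = m$encoding_map[intersect(names(m$encoding_map), analytes)])
}

#' Parse long-format laboratory records
#'
#' Reads a delimited text file (comma- or tab-separated, sniffed from the
#' header line) holding one measurement per row and maps its columns onto the
#' fields case id, analyte id, analyte name, value, unit and (optionally)
#' timestamp. An analyte whose values never parse as numbers is treated as
#' categorical and its tokens are kept verbatim; for numeric analytes, rows
#' whose value fails to parse are dropped with a warning.
#'
#' @param path path to the records file.
#' @param schema named character vector mapping the required field names
#'   (`case_id`, `analyte_id`, `analyte_name`, `value`, `unit`, and optionally
#'   `timestamp`) to the column names used in the file.
#' @return A data frame with one row per retained record and columns
#'   `case_id`, `analyte_id`, `analyte_name`, `value` (character as read),
#'   `value_num` (parsed numeric, `NA` for categorical analytes), `unit`,
#'   `timestamp` and the logical `categorical`.
#' @export
parse_lab_records <- function(path,
                              schema = c(case_id = "case_id",
                                         analyte_id = "analyte_id",
                                         analyte_name = "analyte_name",
                                         value = "value",
                                         unit = "unit",
                                         timestamp = "timestamp")) {
  if (!file.exists(path)) stopf("records file not found: %s", path)
  required <- c("case_id", "analyte_id", "analyte_name", "value", "unit")
  if (!all(required %in% names(schema)))
    stopf("schema must name columns for: %s",
          paste(setdiff(required, names(schema)), collapse = ", "))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(case_id = character(), analyte_id = character(),
                      analyte_name = character(), value = character(),
                      value_num = numeric(), unit = character(),
                      timestamp = numeric(), categorical = logical(),
                      stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[required]), names(raw))
  if (length(missing_cols))
    stopf("records file lacks configured column(s): %s",
          paste(missing_cols, collapse = ", "))
  rec <- data.frame(case_id = trimws(raw[[schema[["case_id"]]]]),
                    analyte_id = trimws(raw[[schema[["analyte_id"]]]]),
                    analyte_name = raw[[schema[["analyte_name"]]]],
                    value = trimws(raw[[schema[["value"]]]]),
                    unit = raw[[schema[["unit"]]]],
                    stringsAsFactors = FALSE)
  ts_col <- if ("timestamp" %in% names(schema)) schema[["timestamp"]] else NULL
  rec$timestamp <- if (!is.null(ts_col) && ts_col %in% names(raw))
    suppressWarnings(as.numeric(raw[[ts_col]])) else NA_real_
  if (any(!nzchar(rec$case_id)) || any(!nzchar(rec$analyte_id)))
    stopf("case_id and analyte_id must be non-empty")
  rec$value_num <- suppressWarnings(as.numeric(rec$value))
  ## an analyte is categorical iff none of its values parse as a number
  parses <- !is.na(rec$value_num)
  cat_analyte <- tapply(parses, rec$analyte_id, function(z) !any(z))
  rec$categorical <- unname(cat_analyte[rec$analyte_id])
  bad <- !rec$categorical & is.na(rec$value_num)
  if (any(bad)) {
    warnf("skipping %d record(s) with unparseable numeric values (analytes: %s)",
          sum(bad), paste(unique(rec$analyte_id[bad]), collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
  }
  rec$value_num[rec$categorical] <- NA_real_
  rownames(rec) <- NULL
  rec
}

#' Pivot laboratory records into a case-by-analyte matrix
#'
#' Duplicate measurements of one analyte within one case are reduced to a
#' single value according to `dedup`. Two-level categorical analytes are
#' encoded numerically (the lexicographically first token is coded 1, the
#' second 0) and the mapping recorded in the matrix's `encoding_map`;
#' categorical analytes with more than two levels are rejected. Mixed units
#' within one analyte are an error rather than silently converted.
#'
#' @param records data frame as returned by [parse_lab_records()].
#' @param dedup duplicate policy: `"first_by_timestamp"` (default; the value
#'   at presentation is the diagnostically relevant one), `"mean"`, or
#'   `"last"`. Records without timestamps fall back to file order.
#' @return A [lab_matrix()].
#' @export
build_lab_matrix <- function(records,
                             dedup = c("first_by_timestamp", "mean", "last")) {
  dedup <- match.arg(dedup)
  if (nrow(records) == 0L) stopf("no records to pivot")
  ## unit consistency per analyte
  unit_tab <- tapply(records$unit, records$analyte_id,
                     function(u) unique(u[nzchar(u) & !is.na(u)]))
  offenders <- names(unit_tab)[vapply(unit_tab, length, 1L) > 1L]
  if (length(offenders))
    stopf("conflicting units for analyte(s): %s",
          paste(vapply(offenders, function(a)
            sprintf("%s (%s)", a, paste(unit_tab[[a]], collapse = " vs ")),
            character(1)), collapse = "; "))

  encoding_map <- list()
  rec <- records
  for (a in unique(rec$analyte_id[rec$categorical])) {
    idx <- rec$analyte_id == a
    levels <- sort(unique(rec$value[idx]))
    if (length(levels) > 2L)
      stopf("categorical analyte '%s' has %d levels; only two are supported",
            a, length(levels))
    codes <- stats::setNames(if (length(levels) == 2L) c(1, 0) else 1, levels)
    encoding_map[[a]] <- codes
    rec$value_num[idx] <- unname(codes[rec$value[idx]])
  }

  cases <- unique(rec$case_id)
  analytes <- unique(rec$analyte_id)
  values <- matrix(NA_real_, length(cases), length(analytes),
                   dimnames = list(cases, analytes))
  ord <- seq_len(nrow(rec))
  key <- paste(rec$case_id, rec$analyte_id, sep = "\r")
  ts <- ifelse(is.na(rec$timestamp), ord, rec$timestamp)
  split_idx <- split(seq_len(nrow(rec)), key)
  for (idx in split_idx) {
    v <- switch(dedup,
                first_by_timestamp = rec$value_num[idx][which.min(ts[idx])],
                last = rec$value_num[idx][which.max(ts[idx])],
                mean = mean(rec$value_num[idx]))
    values[rec$case_id[idx[1L]], rec$analyte_id[idx[1L]]] <- v
  }
  name_of <- tapply(rec$analyte_name, rec$analyte_id, function(x) x[[1L]])
  unit_of <- tapply(rec$unit, rec$analyte_id,
                    function(u) { u <- unique(u[nzchar(u) & !is.na(u)])
                      if (length(u)) u else NA_character_ })
  lab_matrix(values,
             analyte_names = unname(name_of[analytes]),
             units = unname(unit_of[analytes]),
             encoding_map = encoding_map)
}

#' Binary diagnosis labels from ICD-10 code lists
#'
#' A case is labelled 1 when at least one of its diagnosis codes falls, by its
#' three-character category, inside the closed interval
#' `[range_lo, range_hi]` (default I20-I25, the ischemic heart disease block
#' I20.0-I25.90). Primary and secondary diagnoses are not distinguished.
#' Codes are normalized (upper case, whitespace stripped) before matching;
#' codes without a leading letter raise a warning and never match.
#'
#' @param diagnoses a named list mapping case id to a character vector of
#'   ICD-10 codes, or a data frame with columns `case_id` and `codes`
#'   (semicolon-separated).
#' @param range_lo,range_hi three-character ICD-10 category bounds, both
#'   inclusive.
#' @return An object of class `cohort_labels`: a named 0/1 integer vector in
#'   `$labels` plus the target range.
#' @export
label_cases <- function(diagnoses, range_lo = "I20", range_hi = "I25") {
  if (is.data.frame(diagnoses)) {
    if (!all(c("case_id", "codes") %in% names(diagnoses)))
      stopf("diagnoses data frame needs columns case_id and codes")
    diagnoses <- stats::setNames(strsplit(as.character(diagnoses$codes), ";"),
                                 diagnoses$case_id)
  }
  if (nchar(range_lo) != 3L || nchar(range_hi) != 3L)
    stopf("range bounds must be three-character ICD-10 categories")
  labels <- vapply(diagnoses, function(codes) {
    if (length(codes) == 0L) return(0L)
    codes <- toupper(gsub("\\s", "", codes))
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0L) return(0L)
    malformed <- !grepl("^[A-Z][0-9]{2}", codes)
    if (any(malformed))
      warnf("malformed ICD-10 code(s) treated as non-matching: %s",
            paste(codes[malformed], collapse = ", "))
    cat3 <- substr(codes[!malformed], 1L, 3L)
    as.integer(any(cat3 >= range_lo & cat3 <= range_hi))
  }, integer(1))
  structure(list(labels = labels, target_range = c(range_lo, range_hi)),
            class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  cat(sprintf("<cohort_labels> %d cases, %d positive (ICD-10 %s-%s)\n",
              length(x$labels), sum(x$labels),
              x$target_range[1], x$target_range[2]))
  invisible(x)
}

## labels aligned to a matrix's cases; cases without diagnoses are controls
labels_for <- function(labels, cases) {
  out <- labels$labels[cases]
  out[is.na(out)] <- 0L
  stats::setNames(as.integer(out), cases)
}

#' Restrict a cohort to cases with a measured index analyte
#'
#' Mirrors the preselection of the motivating study: only cases for which the
#' index analyte (troponin T) was measured enter the analysis, so that the
#' index analyte has 100% coverage in the retained matrix.
#'
#' @param matrix a [lab_matrix()].
#' @param labels a `cohort_labels` object.
#' @param troponin_id analyte id of the index analyte.
#' @return A list with elements `matrix` and `labels`, both restricted to the
#'   retained cases.
#' @export
filter_troponin_cohort <- function(matrix, labels, troponin_id) {
  if (!troponin_id %in% analyte_ids(matrix))
    stopf("index analyte '%s' not present in the matrix", troponin_id)
  keep <- case_ids(matrix)[matrix$observed[, troponin_id]]
  if (length(keep) == 0L)
    warnf("no case has an observed value for '%s'; returning empty cohort",
          troponin_id)
  m <- subset_lab_matrix(matrix, cases = keep)
  lb <- structure(list(labels = labels_for(labels, keep),
                       target_range = labels$target_range),
                  class = "cohort_labels")
  list(matrix = m, labels = lb)
}

#' Write / read a laboratory matrix as a wide delimited table
#'
#' The wide table uses an empty field (no sentinel value) for missing cells.
#' A sidecar `<path>.meta` key-value file carries analyte display names,
#' units and categorical encodings so that a round trip preserves metadata.
#'
#' @param matrix a [lab_matrix()].
#' @param path output path for the wide tab-separated table.
#' @return `path`, invisibly.
#' @export
write_lab_matrix <- function(matrix, path) {
  df <- data.frame(case_id = case_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  meta <- c(
    sprintf("analyte\t%s\t%s\t%s", analyte_ids(matrix),
            matrix$analyte_names, matrix$units),
    unlist(lapply(names(matrix$encoding_map), function(a) {
      codes <- matrix$encoding_map[[a]]
      sprintf("encoding\t%s\t%s\t%g", a, names(codes), codes)
    })))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_lab_matrix
#' @export
read_lab_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df$case_id)
  analyte_names <- colnames(values)
  units <- rep(NA_character_, ncol(values))
  encoding_map <- list()
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- strsplit(readLines(meta_path), "\t", fixed = TRUE)
    for (row in meta) {
      if (row[1] == "analyte") {
        j <- match(row[2], colnames(values))
        if (!is.na(j)) { analyte_names[j] <- row[3]; units[j] <- row[4] }
      } else if (row[1] == "encoding") {
        encoding_map[[row[2]]] <- c(encoding_map[[row[2]]],
                                    stats::setNames(as.numeric(row[4]), row[3]))
      }
    }
  }
  units[units == "NA"] <- NA_character_
  lab_matrix(values, analyte_names = analyte_names, units = units,
             encoding_map = encoding_map)
}

#' Read a diagnoses file
#'
#' Expects a delimited text file with columns `case_id` and `codes`, the
#' latter holding semicolon-separated ICD-10 codes.
#'
#' @param path path to the diagnoses file.
#' @return A named list mapping case id to a character vector of codes.
#' @export
read_diagnoses <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("case_id", "codes") %in% names(df)))
    stopf("diagnoses file needs columns case_id and codes")
  stats::setNames(strsplit(df$codes, ";"), df$case_id)
}
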