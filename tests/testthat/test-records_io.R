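test_that("parsing maps columns, skips bad numerics, handles empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_fixture(path)
  rec <- parse_lab_records(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$case_id, c("c1", "c1", "c2"))
  expect_equal(rec$value_num, c(12.5, 4.1, 250))
  expect_equal(rec$unit[1], "ng/L")

  ## tab-separated variant is sniffed
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_records_fixture(path2, sep = "\t")
  expect_equal(parse_lab_records(path2)$value_num, rec$value_num)

  ## empty file -> empty record set, not an error
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(parse_lab_records(empty)), 0L)

  ## unparseable numeric for a numeric analyte is skipped with a warning
  writeLines(c("case_id,analyte_id,analyte_name,value,unit,timestamp",
               "c1,k,Potassium,4.1,mmol/L,1",
               "c2,k,Potassium,abc,mmol/L,1"), path)
  expect_warning(rec2 <- parse_lab_records(path), "unparseable")
  expect_equal(nrow(rec2), 1L)

  ## missing configured column is a configuration error
  writeLines(c("patient,analyte_id,analyte_name,value,unit",
               "c1,k,Potassium,4.1,mmol/L"), path)
  expect_error(parse_lab_records(path), "lacks configured column")
})

test_that("matrix pivot respects dedup policy and masks unmeasured cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,analyte_id,analyte_name,value,unit,timestamp",
               "c1,tnt,Troponin T,12.5,ng/L,5",
               "c1,tnt,Troponin T,99,ng/L,2",
               "c1,k,Potassium,4.1,mmol/L,1",
               "c2,tnt,Troponin T,250,ng/L,1",
               "c2,glc,Glucose,6.0,mmol/L,1"), path)
  rec <- parse_lab_records(path)
  m <- build_lab_matrix(rec, dedup = "first_by_timestamp")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m$values["c1", "tnt"], 99)   # earlier timestamp wins
  expect_true(is.na(m$values["c1", "glc"]))
  expect_false(m$observed["c2", "k"])

  expect_equal(build_lab_matrix(rec, dedup = "last")$values["c1", "tnt"], 12.5)
  expect_equal(build_lab_matrix(rec, dedup = "mean")$values["c1", "tnt"],
               (12.5 + 99) / 2)

  ## full coverage -> all-true mask
  m2 <- build_lab_matrix(rec[rec$analyte_id == "tnt", ])
  expect_true(all(m2$observed))
})

test_that("categorical analytes are binary-encoded with a recorded mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,analyte_id,analyte_name,value,unit,timestamp",
               "c1,coll,Collection,arterial,,1",
               "c2,coll,Collection,venous,,1",
               "c1,k,Potassium,4.1,mmol/L,1",
               "c2,k,Potassium,4.4,mmol/L,1"), path)
  m <- build_lab_matrix(parse_lab_records(path))
  expect_equal(m$encoding_map$coll, c(arterial = 1, venous = 0))
  expect_equal(unname(m$values[, "coll"]), c(1, 0))

  ## three-level categorical is rejected
  writeLines(c("case_id,analyte_id,analyte_name,value,unit,timestamp",
               "c1,coll,Collection,arterial,,1",
               "c2,coll,Collection,venous,,1",
               "c3,coll,Collection,capillary,,1"), path)
  expect_error(build_lab_matrix(parse_lab_records(path)), "levels")
})

test_that("conflicting units for one analyte are an error naming it", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,analyte_id,analyte_name,value,unit,timestamp",
               "c1,glc,Glucose,6.0,mmol/L,1",
               "c2,glc,Glucose,108,mg/dL,1"), path)
  expect_error(build_lab_matrix(parse_lab_records(path)),
               "conflicting units.*glc")
})

test_that("pivot round-trips the retained record values exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_fixture(path)
  rec <- parse_lab_records(path)
  m <- build_lab_matrix(rec)
  for (i in seq_len(nrow(rec)))
    expect_identical(m$values[rec$case_id[i], rec$analyte_id[i]],
                     rec$value_num[i])
})

test_that("ICD-10 labelling matches the closed category interval", {
  d <- list(p1 = c("I21.4", "E11.9"),   # in range
            p2 = "I25.90",              # upper boundary inclusive
            p3 = "J18.9",               # outside
            p4 = character(0),          # no diagnoses
            p5 = c(" i20.0 "),          # normalization
            p6 = "I19.9", p7 = "I26.0") # adjacent categories outside
  lb <- label_cases(d)
  expect_equal(unname(lb$labels[c("p1","p2","p3","p4","p5","p6","p7")]),
               c(1L, 1L, 0L, 0L, 1L, 0L, 0L))

  ## malformed code warns and never matches
  expect_warning(lb2 <- label_cases(list(q = "20.0I")), "malformed")
  expect_equal(unname(lb2$labels), 0L)

  ## idempotent and order/case insensitive
  expect_equal(unname(label_cases(list(a = c("e11.9", "I21.4")))$labels),
               unname(label_cases(list(a = c("I21.4", "E11.9")))$labels))
})

test_that("troponin cohort filter retains exactly the measured cases", {
  v <- matrix(c(1, NA, 3, NA, 5,
                10, 20, NA, 40, 50), ncol = 2,
              dimnames = list(sprintf("c%d", 1:5), c("tnt", "k")))
  m <- lab_matrix(v)
  lb <- label_cases(list(c1 = "I21.0", c2 = "I21.0", c3 = "J18.9",
                         c4 = "J18.9", c5 = "I25.1"))
  out <- filter_troponin_cohort(m, lb, "tnt")
  expect_equal(rownames(out$matrix$values), c("c1", "c3", "c5"))
  expect_equal(unname(out$labels$labels), c(1L, 0L, 1L))
  ## index analyte fully observed afterwards
  expect_true(all(out$matrix$observed[, "tnt"]))

  expect_error(filter_troponin_cohort(m, lb, "nope"), "not present")
  ## all-observed input is the identity
  m2 <- lab_matrix(matrix(1:4, 2, dimnames = list(c("a","b"), c("tnt","k"))) * 1.0)
  out2 <- filter_troponin_cohort(m2, label_cases(list(a = "I20.0", b = "J18.9")), "tnt")
  expect_equal(out2$matrix$values, m2$values)
  ## none observed -> empty with warning
  m3 <- lab_matrix(matrix(c(NA, NA, 1, 2), 2,
                          dimnames = list(c("a","b"), c("tnt","k"))))
  expect_warning(out3 <- filter_troponin_cohort(
    m3, label_cases(list(a = "I20.0", b = "J18.9")), "tnt"), "no case")
  expect_equal(nrow(out3$matrix$values), 0L)
})

test_that("wide-matrix export round-trips values, mask and metadata", {
  v <- matrix(c(1.5, NA, 3, 4, NA, 6), 3,
              dimnames = list(c("c1","c2","c3"), c("tnt","coll")))
  m <- lab_matrix(v, analyte_names = c("Troponin T", "Collection"),
                  units = c("ng/L", ""),
                  encoding_map = list(coll = c(arterial = 1, venous = 0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lab_matrix(m, path)
  m2 <- read_lab_matrix(path)
  expect_equal(m2$values, m$values)
  expect_equal(m2$observed, m$observed)
  expect_equal(unname(m2$analyte_names), c("Troponin T", "Collection"))
  expect_equal(m2$encoding_map$coll, m$encoding_map$coll)
})
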