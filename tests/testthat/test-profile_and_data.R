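test_that("CSV reading preserves missingness and reports parse errors with coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,M1,M2", "S1,10,40", "S2,20,", "S3,30,60"), f)
  m <- read_measurement_matrix(f, "CSV")
  expect_equal(sum(is.na(m$values)), 1L)
  expect_true(is.na(m$values["S2", "M2"]))
  expect_equal(dim(m$values), c(3L, 2L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,M1", "S1,10", "S2,oops"), bad)
  expect_error(read_measurement_matrix(bad, "CSV"), "S2.*M1|M1.*S2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,M1", "S1,10", "S1,20"), dup)
  expect_error(read_measurement_matrix(dup, "CSV"), "S1")
})

test_that("NEXUS continuous dialect is equivalent to CSV and rejects other features", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,M1,M2", "S1,10.5,40", "S2,20,NA", "S3,30,60.25"), csv)
  m_csv <- read_measurement_matrix(csv, "CSV")

  nex <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               "  DIMENSIONS NTAX=3 NCHAR=2;",
               "  FORMAT DATATYPE=CONTINUOUS MISSING=?;",
               "  CHARLABELS M1 M2;",
               "  MATRIX",
               "    S1 10.5 40", "    S2 20 ?", "    S3 30 60.25",
               "  ;", "END;"), nex)
  m_nex <- read_measurement_matrix(nex, "NEXUS_CONTINUOUS")
  expect_identical(m_nex$values, m_csv$values)

  disc <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               "  DIMENSIONS NTAX=1 NCHAR=2;",
               "  FORMAT DATATYPE=STANDARD;",
               "  MATRIX", "    S1 0 1", "  ;", "END;"), disc)
  expect_error(read_measurement_matrix(disc, "NEXUS_CONTINUOUS"), "CONTINUOUS")
})

test_that("write/read round-trips are bit-for-bit in every dialect", {
  set.seed(11)
  v <- matrix(stats::rnorm(30) * exp(stats::rnorm(30)), 5, 6,
              dimnames = list(paste0("S", 1:5), paste0("M", 1:6)))
  v[sample(length(v), 7)] <- NA
  m <- measurement_matrix(v)
  for (dialect in c("CSV", "TSV", "NEXUS_CONTINUOUS")) {
    f <- withr::local_tempfile()
    write_measurement_matrix(m, f, dialect)
    back <- read_measurement_matrix(f, dialect)
    expect_identical(back$values, m$values, label = dialect)
  }
})

test_that("packaged profile satisfies the published composition", {
  profile <- load_profile()
  expect_equal(nrow(profile), 18L)
  expect_equal(length(unique(profile$phenotype_id)), 12L)
  expect_equal(sum(profile$reference_group == "AMH"), 12L)
  expect_equal(sum(profile$reference_group == "NEANDERTHAL"), 6L)
  # 14 linear vs 4 nonlinear predictions, as in a fully preserved subject
  expect_equal(as.vector(table(profile$measurement_class)[c("LINEAR", "NONLINEAR")]),
               c(14L, 4L))
})

test_that("profile validation rejects malformed inputs", {
  empty <- withr::local_tempfile()
  writeLines("prediction_id\tphenotype_id\tmeasurement_id\treference_group\tdirection\tlineage_origin\tmeasurement_class",
             empty)
  expect_error(load_profile(empty), "empty")

  bad_dir <- withr::local_tempfile()
  writeLines(c("prediction_id\tphenotype_id\tmeasurement_id\treference_group\tdirection\tlineage_origin\tmeasurement_class",
               "P1\tph1\tM1\tAMH\t2\tAMH_DERIVED\tLINEAR"), bad_dir)
  expect_error(load_profile(bad_dir), "direction")

  bad_ref <- withr::local_tempfile()
  writeLines(c("prediction_id\tphenotype_id\tmeasurement_id\treference_group\tdirection\tlineage_origin\tmeasurement_class",
               "P1\tph1\tM1\tDENISOVAN\t1\tAMH_DERIVED\tLINEAR"), bad_ref)
  expect_error(load_profile(bad_ref), "reference group")
})

test_that("test-subject selection applies the adult and testability criteria", {
  records <- data.frame(
    specimen_id = c("T1", "T2", "T3", "R1"),
    group = c("TEST", "TEST", "TEST", "AMH"),
    is_adult = c(TRUE, TRUE, FALSE, TRUE),
    n_testable = c(4L, 5L, 18L, 0L),
    stringsAsFactors = FALSE
  )
  kept <- select_test_subjects(records)
  expect_false("T1" %in% kept$specimen_id)  # fewer than five testable
  expect_true("T2" %in% kept$specimen_id)   # boundary inclusive
  expect_false("T3" %in% kept$specimen_id)  # subadult
  expect_true("R1" %in% kept$specimen_id)   # reference untouched
  # subset and monotone in the threshold
  for (th in 0:19) {
    k <- select_test_subjects(records, th)
    expect_true(all(k$specimen_id %in% records$specimen_id))
    expect_true(all(select_test_subjects(records, th + 1)$specimen_id %in%
                      k$specimen_id))
  }
})

test_that("cranial-capacity normalization scales linear measurements only", {
  v <- matrix(c(30, 60, 118, 121), 2, 2,
              dimnames = list(c("S1", "S2"), c("LEN", "ANG")))
  m <- measurement_matrix(v, classes = c(LEN = "LINEAR", ANG = "NONLINEAR"),
                          capacity = c(S1 = 27, S2 = 1))
  norm <- normalize_by_cranial_capacity(m)
  expect_equal(norm$values["S1", "LEN"], 10)   # 30 / 27^(1/3)
  expect_equal(norm$values["S1", "ANG"], 118)  # nonlinear untouched
  expect_equal(norm$values["S2", "LEN"], 60)   # capacity 1 is identity
  # identity when all capacities are 1
  m1 <- measurement_matrix(v, classes = c(LEN = "LINEAR", ANG = "NONLINEAR"),
                           capacity = c(S1 = 1, S2 = 1))
  expect_equal(normalize_by_cranial_capacity(m1)$values, v)
  # missing capacity for a specimen with linear data names the specimen
  m2 <- measurement_matrix(v, classes = c(LEN = "LINEAR", ANG = "NONLINEAR"),
                           capacity = c(S1 = 27, S2 = NA))
  expect_error(normalize_by_cranial_capacity(m2), "S2")
  # missingness pattern is preserved
  v3 <- v; v3[1, 1] <- NA
  m3 <- measurement_matrix(v3, classes = c(LEN = "LINEAR", ANG = "NONLINEAR"),
                           capacity = c(S1 = 8, S2 = 8))
  expect_identical(is.na(normalize_by_cranial_capacity(m3)$values), is.na(v3))
})
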