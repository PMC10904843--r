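test_that("read_cohort round-trips a clean fixture with zero rejects", {
  dir <- withr::local_tempdir()
  pats <- patients_df(c("PID000001", "PID000002", "PID000003", "PID000004"),
                      sex = c("male", "female", "male", "female"),
                      race = c("chinese", "malay", "indian", "other"),
                      dob = c("1980-01-01", "1990-05-20", "2004-02-29",
                              "1955-12-31"))
  write_cohort(make_cohort(pats), dir)
  cohort <- read_cohort_dir(dir)
  expect_equal(nrow(cohort$patients), 4)
  expect_equal(nrow(cohort$rejects), 0)
  expect_s3_class(cohort$patients$date_of_birth, "Date")
})

test_that("invalid rows are rejected with diagnostics, never coerced", {
  dir <- withr::local_tempdir()
  tabs <- empty_cohort_tables("PID000001")
  tabs$labs <- labs_df(c("PID000001", "PID000001"), c(-1.2, 3.1))
  write_cohort(do.call(make_cohort, tabs), dir)
  # write a raw negative-value row (make_cohort would already drop it)
  writeLines(c("patient_id,analyte,value,units,draw_date",
               "PID000001,LDL_C,-1.2,mmol/L,2020-06-01",
               "PID000001,LDL_C,3.1,mmol/L,2020-06-01"),
             file.path(dir, "labs.csv"))
  suppressMessages(cohort <- read_cohort_dir(dir))
  expect_equal(nrow(cohort$labs), 1)
  expect_equal(sum(cohort$rejects$reason == "negative or non-numeric value"), 1)
})

test_that("referential integrity and enum violations are rejected row-wise", {
  dir <- withr::local_tempdir()
  write_cohort(make_cohort(patients_df("PID000001")), dir)
  writeLines(c("patient_id,code,code_system,description,entry_date",
               "PID000009,C1,local,orphan row,2020-01-01",
               "PID000001,C2,ICD10,bad system,2020-01-01",
               "PID000001,C3,local,fine,2020-13-45",
               "PID000001,C4,SNOMED,fine,2020-01-01"),
             file.path(dir, "problems.csv"))
  suppressMessages(cohort <- read_cohort_dir(dir))
  expect_equal(nrow(cohort$problems), 1)
  expect_setequal(cohort$rejects$reason,
                  c("patient_id not in patients table", "unknown code_system",
                    "malformed entry_date"))
})

test_that("LDL-C in mg/dL is converted to mmol/L on read", {
  dir <- withr::local_tempdir()
  write_cohort(make_cohort(patients_df("PID000001")), dir)
  writeLines(c("patient_id,analyte,value,units,draw_date",
               "PID000001,LDL_C,189.48,mg/dL,2020-06-01",
               "PID000001,LDL_C,5.0,IU,2020-06-01"),
             file.path(dir, "labs.csv"))
  suppressMessages(cohort <- read_cohort_dir(dir))
  expect_equal(cohort$labs$value, 189.48 / 38.67)
  expect_equal(cohort$labs$units, "mmol/L")
  expect_equal(sum(cohort$rejects$reason == "unconvertible LDL-C units"), 1)
})

test_that("write_cohort then read_cohort is the identity on generated cohorts", {
  for (seed in c(11, 12)) {
    sc <- generate_cohort(synthetic_config(
      n_patients = 120, seed = seed,
      fabry = list(n_known = 1, n_suspect = 4),
      fh = list(n_known = 2, n_suspect = 10), n_near_miss = 8))
    dir <- withr::local_tempdir()
    write_cohort(sc$cohort, dir)
    back <- read_cohort_dir(dir)
    for (tab in c("patients", "problems", "labs", "meds"))
      expect_equal(back[[tab]], sc$cohort[[tab]], label = tab)
  }
})

test_that("pseudonymise is a seeded bijection onto PID labels", {
  expect_equal(unname(pseudonymise("S1234567A", seed = 99)), "PID000001")
  m1 <- pseudonymise(c("S1A", "S2B", "S3C"), seed = 4)
  m2 <- pseudonymise(c("S1A", "S2B", "S3C"), seed = 4)
  expect_identical(m1, m2)
  expect_error(pseudonymise(c("dup", "dup")), "duplicate")

  ids <- sprintf("S%07dZ", seq_len(1000))
  map <- pseudonymise(ids, seed = 7)
  # brute-force bijection check: injective and covering PID000001..PID001000
  expect_equal(sort(unname(map)), sprintf("PID%06d", 1:1000))
  expect_true(all(grepl("^PID[0-9]{6}$", map)))
  # output labels never leak any input id as a substring
  expect_false(any(vapply(ids, function(i) any(grepl(i, map, fixed = TRUE)),
                          logical(1))))
})

test_that("age_at matches a calendar-anniversary oracle, incl. 29 Feb", {
  expect_equal(age_at("2000-06-15", "2050-06-14"), 49)
  expect_equal(age_at("2000-06-15", "2050-06-15"), 50)
  expect_error(age_at("2000-01-01", "1999-12-31"), "after reference")

  # independent oracle: largest a such that the a-th calendar anniversary
  # (29 Feb rolling to 1 Mar in non-leap years) is <= reference
  anniversary <- function(dob, a) {
    d <- as.POSIXlt(dob)
    cand <- as.Date(sprintf("%d-%02d-%02d", d$year + 1900 + a, d$mon + 1,
                            d$mday), format = "%Y-%m-%d")
    if (is.na(cand))  # 29 Feb in a non-leap year rolls to 1 Mar
      cand <- as.Date(sprintf("%d-03-01", d$year + 1900 + a))
    cand
  }
  oracle <- function(dob, ref) {
    a <- 0
    while (anniversary(dob, a + 1) <= ref) a <- a + 1
    a
  }
  dobs <- as.Date(c("2000-02-29", "1996-02-29", "2001-03-01", "1999-12-31"))
  refs <- seq(as.Date("2002-02-26"), as.Date("2002-03-03"), by = "day")
  for (dob in dobs) for (ref in refs) {
    dob <- as.Date(dob, origin = "1970-01-01")
    ref <- as.Date(ref, origin = "1970-01-01")
    expect_equal(age_at(dob, ref), oracle(dob, ref),
                 label = sprintf("dob %s ref %s", dob, ref))
  }
})

test_that("age_at is monotone non-decreasing in the reference date", {
  set.seed(31)
  dobs <- as.Date("1960-01-01") + sample.int(15000, 20)
  for (dob in dobs) {
    dob <- as.Date(dob, origin = "1970-01-01")
    refs <- seq(dob, by = "month", length.out = 40)
    ages <- age_at(dob, refs)
    expect_true(all(diff(ages) >= 0))
  }
})

test_that("data_window validates its bounds", {
  expect_error(data_window("2022-01-01", "2018-01-01"), "precede")
  w <- data_window()
  expect_equal(as.character(w$start), "2018-01-01")
  expect_equal(as.character(w$end), "2022-03-01")
})
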