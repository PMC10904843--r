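catalog <- default_catalog()
rules <- fh_rules()

test_that("premature ASCVD uses the earliest event and strict sex cutoffs", {
  win <- data_window()
  # male with MI at completed age 54 -> premature; at 55 -> not
  pat <- patients_df("a", sex = "male", dob = "1966-03-10")
  mi54 <- problems_df("a", "myocardial infarction", date = "2021-03-09")
  mi55 <- problems_df("a", "myocardial infarction", date = "2021-03-10")
  expect_equal(is_premature_ascvd(pat, mi54, catalog, rules = rules),
               list(premature = TRUE, rule = "ascvd_male_lt55"))
  expect_equal(is_premature_ascvd(pat, mi55, catalog, rules = rules),
               list(premature = FALSE, rule = NA_character_))
  # female cutoff is 60
  patf <- patients_df("a", sex = "female", dob = "1966-03-10")
  expect_true(is_premature_ascvd(patf, mi55, catalog, rules = rules)$premature)
  # unknown sex: rule not applicable
  patu <- patients_df("a", sex = "unknown", dob = "1966-03-10")
  expect_message(
    r <- is_premature_ascvd(patu, mi54, catalog, rules = rules),
    "not applicable")
  expect_false(r$premature)
})

test_that("premature ASCVD agrees with a brute-force min-age scan", {
  set.seed(77)
  win <- data_window()
  for (rep in 1:30) {
    sex <- sample(c("male", "female"), 1)
    dob <- win$end - sample(15000:25000, 1)
    n <- sample(1:5, 1)
    dates <- win$start + sample.int(as.integer(win$end - win$start), n)
    desc <- sample(c("myocardial infarction", "angina", "osteoarthritis"), n,
                   replace = TRUE)
    pat <- patients_df("a", sex = sex, dob = format(dob))
    probs <- problems_df(rep("a", n), desc, date = format(dates))
    got <- is_premature_ascvd(pat, probs, catalog, rules = rules)$premature
    is_ascvd <- desc %in% c("myocardial infarction", "angina")
    expected <- if (!any(is_ascvd)) FALSE else {
      age <- age_at(dob, min(dates[is_ascvd]))
      age < if (sex == "male") 55 else 60
    }
    expect_equal(got, expected)
  }
})

test_that("high-intensity statin coverage respects drug, dose and interval", {
  draw <- as.Date("2020-06-01")
  m <- function(drug, dose, start, end)
    make_cohort(patients_df("a"), meds = meds_df("a", drug, dose, start, end))$meds
  expect_true(on_high_intensity_statin(
    m("atorvastatin", 80, "2020-01-01", "2020-12-31"), draw, rules))
  expect_false(on_high_intensity_statin(
    m("atorvastatin", 20, "2020-01-01", "2020-12-31"), draw, rules))
  expect_false(on_high_intensity_statin(
    m("atorvastatin", 80, "2020-07-01", "2020-12-31"), draw, rules))
  # open-ended order covers any later date
  expect_true(on_high_intensity_statin(
    m("Rosuvastatin", 20, "2020-01-01", ""), draw, rules))
  expect_false(on_high_intensity_statin(
    m("simvastatin", 80, "2020-01-01", "2020-12-31"), draw, rules))
})

test_that("statin coverage agrees with brute-force interval containment", {
  set.seed(88)
  win <- data_window()
  his <- rules$high_intensity_statins
  for (rep in 1:30) {
    n <- sample(1:4, 1)
    start <- win$start + sample.int(1200, n)
    end <- start + sample.int(400, n)
    drug <- sample(c("atorvastatin", "rosuvastatin", "simvastatin"), n, TRUE)
    dose <- sample(c(5, 10, 20, 40, 80), n, TRUE)
    meds <- make_cohort(patients_df("a"),
                        meds = meds_df(rep("a", n), drug, dose,
                                       format(start), format(end)))$meds
    date <- win$start + sample.int(1600, 1)
    expected <- FALSE
    for (i in seq_len(n)) {
      j <- match(drug[i], his$drug_name)
      if (!is.na(j) && dose[i] >= his$min_dose_mg[j] &&
          start[i] <= date && end[i] >= date) expected <- TRUE
    }
    expect_equal(on_high_intensity_statin(meds, date, rules), expected)
  }
})

test_that("flag_fh applies strict thresholds and age-banded LDL rules", {
  # exactly 4.9 at age 30: no rule fires (strict >)
  pat30 <- patients_df("a", dob = "1990-06-01")
  r <- flag_fh(pat30, problems_df(), labs_df("a", 4.9), meds_df())
  expect_equal(r$status, "negative")
  expect_length(r$triggered_rules, 0)

  # age 17, LDL 4.0 -> child rule
  pat17 <- patients_df("a", dob = "2004-01-01")
  r2 <- flag_fh(pat17, problems_df(), labs_df("a", 4.0, date = "2021-06-01"),
                meds_df())
  expect_equal(r2$status, "suspect")
  expect_equal(r2$triggered_rules, "ldl_child_gt3.9")
  expect_equal(r2$qualifying_ldl, 4.0)

  # LDL 3.0 fires only with an active high-intensity statin
  r3 <- flag_fh(pat30, problems_df(), labs_df("a", 3.0), meds_df())
  expect_equal(r3$status, "negative")
  r4 <- flag_fh(pat30, problems_df(), labs_df("a", 3.0),
                meds_df("a", "atorvastatin", 40))
  expect_equal(r4$triggered_rules, "ldl_statin_gt2.6")

  # FH diagnosis preempts suspect status
  r5 <- flag_fh(pat30, problems_df("a", "familial hypercholesterolemia"),
                labs_df("a", 6.5), meds_df())
  expect_equal(r5$status, "known_case")
  expect_length(r5$triggered_rules, 0)
})

test_that("per-result age uses the draw date, not the window end", {
  # patient crosses 18 mid-window: an LDL of 4.0 qualifies via the child rule
  # only for the draw taken while they were still 18
  pat <- patients_df("a", dob = "2001-06-01")  # turns 18 on 2019-06-01
  early <- flag_fh(pat, problems_df(), labs_df("a", 4.0, date = "2019-05-01"),
                   meds_df())
  late <- flag_fh(pat, problems_df(), labs_df("a", 4.0, date = "2021-05-01"),
                  meds_df())
  expect_equal(early$triggered_rules, "ldl_child_gt3.9")
  expect_equal(late$status, "negative")
})

test_that("qualifying_ldl is the maximum among rule-firing results", {
  pat <- patients_df("a", dob = "1980-01-01")
  labs <- labs_df(rep("a", 3), c(5.2, 6.8, 3.0),
                  date = c("2020-01-01", "2020-06-01", "2020-09-01"))
  r <- flag_fh(pat, problems_df(), labs, meds_df())
  expect_equal(r$qualifying_ldl, 6.8)
})

test_that("screen_fh_cohort handles edge cohorts and recovers plants", {
  empty <- make_cohort(patients_df(character(0)))
  scr <- screen_fh_cohort(empty)
  expect_equal(c(scr$n_known, scr$n_suspect), c(0, 0))

  known_only <- make_cohort(
    patients_df(c("a", "b"), dob = "1980-01-01"),
    problems_df(c("a", "b"), rep("familial hypercholesterolaemia", 2)),
    labs_df(c("a", "b"), c(8.0, 9.0)))
  scr2 <- screen_fh_cohort(known_only)
  expect_equal(scr2$n_known, 2)
  expect_equal(scr2$n_suspect, 0)

  sc <- generate_cohort(synthetic_config(
    n_patients = 700, seed = 161500,
    fabry = list(n_known = 0, n_suspect = 0),
    fh = list(n_known = 161, n_suspect = 500), n_near_miss = 0))
  scr3 <- screen_fh_cohort(sc$cohort)
  expect_equal(scr3$n_known, 161)
  expect_equal(scr3$n_suspect, 500)
  exp <- raredetect:::truth_expectations(sc$truth)
  expect_equal(scr3$results$status, exp$fh_expected)
})

test_that("adding a lab result never demotes a suspect", {
  set.seed(99)
  pat <- patients_df("a", dob = "1975-03-03")
  for (rep in 1:15) {
    n <- sample(1:4, 1)
    vals <- round(runif(n, 1, 8), 2)
    labs <- labs_df(rep("a", n), vals,
                    date = format(as.Date("2019-01-01") + sample.int(900, n)))
    base <- flag_fh(pat, problems_df(), labs, meds_df())
    more <- flag_fh(pat, problems_df(),
                    rbind(labs, labs_df("a", round(runif(1, 1, 8), 2))),
                    meds_df())
    if (base$status == "suspect") expect_equal(more$status, "suspect")
    # suspects carry >=1 triggered rule; negatives none
    expect_equal(base$status == "suspect", length(base$triggered_rules) > 0)
  }
})

test_that("fh_rules validates threshold ordering", {
  expect_warning(fh_rules(ldl_on_statin = 5.0), "ordering")
  expect_error(fh_rules(ldl_adult = -1), "positive")
})
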