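test_that("interaction_counts uses superset-containment semantics", {
  ps <- list(a = c("kidney", "cardiac"), b = "kidney")
  k2 <- interaction_counts(ps, 2)
  expect_equal(k2$count[k2$combination == "kidney+cardiac"], 1)
  expect_equal(sum(k2$count), 1)
  k1 <- interaction_counts(ps, 1)
  expect_equal(k1$count[k1$combination == "kidney"], 2)
  expect_equal(k1$count[k1$combination == "cardiac"], 1)
  expect_error(interaction_counts(ps, 6), "1..5")
})

test_that("venn_regions counts exact sets only", {
  vr <- venn_regions(list(a = c("kidney", "cardiac")))
  expect_equal(vr$count[vr$region == "kidney+cardiac"], 1)
  expect_equal(sum(vr$count), 1)
  vr0 <- venn_regions(list())
  expect_equal(nrow(vr0), 31)
  expect_true(all(vr0$count == 0))
})

test_that("interaction and venn counts match brute force and the inclusion identity", {
  set.seed(123)
  subsets <- unlist(lapply(1:5, function(k)
    utils::combn(raredetect:::SYSTEMS, k, simplify = FALSE)), recursive = FALSE)
  for (rep in 1:30) {
    ps <- random_system_sets(sample(10:120, 1))
    vr <- venn_regions(ps)
    for (k in 1:5) {
      ik <- interaction_counts(ps, k)
      for (i in seq_len(nrow(ik))) {
        C <- strsplit(ik$combination[i], "+", fixed = TRUE)[[1]]
        brute <- sum(vapply(ps, function(s) all(C %in% s), logical(1)))
        expect_equal(ik$count[i], brute)
        # inclusion identity: order-k count = sum of venn regions over supersets
        sup <- vapply(subsets, function(S) all(C %in% S), logical(1))
        expect_equal(ik$count[i], sum(vr$count[sup]))
      }
    }
    # regions partition the patients with at least one system
    expect_equal(sum(vr$count), sum(lengths(ps) > 0))
  }
})

test_that("k=2 counts are bounded by their k=1 margins", {
  set.seed(321)
  ps <- random_system_sets(150)
  k1 <- interaction_counts(ps, 1)
  k2 <- interaction_counts(ps, 2)
  for (i in seq_len(nrow(k2))) {
    pair <- strsplit(k2$combination[i], "+", fixed = TRUE)[[1]]
    expect_lte(k2$count[i], min(k1$count[match(pair, k1$combination)]))
  }
})

test_that("demographics_summary computes proportions, medians and IQRs", {
  pats <- patients_df(sprintf("p%d", 1:5),
                      sex = c("male", "male", "male", "female", "female"),
                      race = c("chinese", "chinese", "malay", "indian", "other"),
                      dob = c("1982-03-01", "1980-03-01", "1975-01-01",
                              "1990-01-01", "1985-06-15"))
  ds <- demographics_summary(pats, reference_date = "2022-03-01")
  expect_equal(unname(ds$sex_props[c("male", "female")]), c(0.6, 0.4))
  expect_equal(sum(ds$race_props), 1, tolerance = 1e-9)
  # male ages at 2022-03-01: 40, 42, 47 -> median 42
  m <- ds$age_by_sex[ds$age_by_sex$sex == "male", ]
  expect_equal(m$median, 42)
  # even-n midpoint convention
  ds2 <- demographics_summary(pats[1:2, ], reference_date = "2022-03-01")
  expect_equal(ds2$age_by_sex$median[ds2$age_by_sex$sex == "male"], 41)
  # empty subset: empty summary, not an error
  ds0 <- demographics_summary(pats, character(0))
  expect_equal(ds0$n, 0)
  expect_error(demographics_summary(pats, "nope"), "subset")
})

test_that("two_sample_t_test matches stats::t.test to 1e-10 on random pairs", {
  set.seed(2718)
  for (rep in 1:100) {
    a <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- two_sample_t_test(a, b, "welch")
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(w$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$degrees_of_freedom, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
    p <- two_sample_t_test(a, b, "pooled")
    refp <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(p$t_statistic, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(p$p_value, refp$p.value, tolerance = 1e-10)
  }
})

test_that("t-test degenerate and symmetry cases", {
  expect_equal(two_sample_t_test(c(1, 2, 3), c(1, 2, 3), "pooled")$t_statistic, 0)
  r <- two_sample_t_test(c(4, 5, 6), c(4, 5, 6), "welch")
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(two_sample_t_test(1, c(1, 2)), "n >= 2")
  expect_error(two_sample_t_test(c(2, 2), c(3, 3)), "zero variance")

  set.seed(11)
  a <- rnorm(10); b <- rnorm(15, 1)
  ab <- two_sample_t_test(a, b)
  ba <- two_sample_t_test(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  shifted <- two_sample_t_test(a + 5, b + 5)
  expect_equal(shifted$p_value, ab$p_value, tolerance = 1e-12)
})

test_that("prevalence, percent increase and expected cases arithmetic", {
  expect_equal(prevalence_one_in_n(4, 1280000), 320000)
  expect_equal(prevalence_one_in_n(161, 1280000, round_to = 1000), 8000)
  expect_equal(prevalence_one_in_n(1, 100), 100)
  expect_error(prevalence_one_in_n(0, 100), "zero cases")

  expect_equal(percent_increase(2, 4), 50)
  expect_equal(percent_increase(0, 4), 0)
  expect_equal(percent_increase(3, 4), 75)
  expect_error(percent_increase(1, 0), "positive")

  expect_equal(expected_cases(1280000, 1e-5, "ceil"), 13)
  expect_equal(expected_cases(100, 0.01, "nearest"), 1)
  expect_equal(expected_cases(1280000, 1 / 250, "nearest"), 5120)
  expect_error(expected_cases(100, 0), "in \\(0, 1\\)")
})
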