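# Cohort analytics over screen output: organ-system interaction counts
# (superset containment, the "bar graph" semantics), exact Venn-region
# counts, demographics, the LDL-C two-sample t-test, and the prevalence /
# expected-case arithmetic used when interpreting screen yields.

all_combinations <- function(k) {
  utils::combn(SYSTEMS, k, simplify = FALSE)
}

combo_label <- function(sets) {
  vapply(sets, function(s) paste(SYSTEMS[SYSTEMS %in% s], collapse = "+"),
         character(1))
}

#' Order-k system interaction counts
#'
#' For every combination `C` of `k` organ systems, counts the patients whose
#' affected-system set CONTAINS `C` (superset semantics — a patient with
#' three systems contributes to three two-way interactions). This is the
#' quantity shown in first/second/third-order interaction bar graphs, as
#' opposed to exact Venn regions ([venn_regions()]).
#'
#' @param patient_systems Named list mapping patient id to a character
#'   vector of affected systems (subset of kidney, cardiac, neuro, skin,
#'   eye); e.g. the `systems` element of a [screen_fabry_cohort()] result.
#' @param k Interaction order, 1 to 5.
#' @return Data frame with `combination` (`+`-joined, canonical order) and
#'   `count`, covering all `choose(5, k)` combinations.
#' @export
interaction_counts <- function(patient_systems, k) {
  if (!(length(k) == 1 && k %in% 1:5)) stop("k must be a single integer in 1..5")
  combos <- all_combinations(k)
  # membership matrix route: count(C) = patients whose row covers all of C
  m <- matrix(FALSE, nrow = length(patient_systems), ncol = 5,
              dimnames = list(NULL, SYSTEMS))
  for (i in seq_along(patient_systems))
    m[i, patient_systems[[i]]] <- TRUE
  counts <- vapply(combos, function(C)
    sum(rowSums(m[, C, drop = FALSE]) == length(C)), numeric(1))
  data.frame(combination = combo_label(combos), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Exact Venn-region counts over the five systems
#'
#' The region for subset `S` counts patients whose affected-system set
#' EQUALS `S` exactly. The 31 non-empty regions partition the patients with
#' at least one affected system; for any combination `C`, the order-k
#' interaction count equals the sum of regions over supersets of `C`.
#'
#' @inheritParams interaction_counts
#' @return Data frame with `region` (`+`-joined) and `count` for all 31
#'   non-empty subsets.
#' @export
venn_regions <- function(patient_systems) {
  subsets <- unlist(lapply(1:5, all_combinations), recursive = FALSE)
  keys <- combo_label(subsets)
  pat_keys <- vapply(patient_systems, function(s)
    paste(SYSTEMS[SYSTEMS %in% s], collapse = "+"), character(1))
  tab <- table(factor(pat_keys[nzchar(pat_keys)], levels = keys))
  data.frame(region = keys, count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Demographic summary of a patient subset
#'
#' Sex and race counts with proportions over non-missing values (`unknown`
#' is reported in counts but excluded from proportions), plus per-sex age
#' median and IQR at a reference date. Median uses the midpoint convention
#' for even n; quartiles use linear interpolation (type 7), so IQRs are
#' reproducible.
#'
#' @param patients Patients data frame.
#' @param subset_ids Patient ids to summarise (default: all).
#' @param reference_date Date at which ages are computed (default: the
#'   standard window end).
#' @return A list of class `demographics_summary` with `n`, `sex_counts`,
#'   `sex_props`, `race_counts`, `race_props`, and `age_by_sex` (data frame
#'   `sex`, `n`, `median`, `q1`, `q3`, `iqr`).
#' @export
demographics_summary <- function(patients, subset_ids = NULL,
                                 reference_date = data_window()$end) {
  if (is.null(subset_ids)) subset_ids <- patients$patient_id
  if (!all(subset_ids %in% patients$patient_id))
    stop("subset_ids must be a subset of the cohort's patient ids")
  p <- patients[patients$patient_id %in% subset_ids, , drop = FALSE]
  prop_of <- function(counts, missing_level) {
    lv <- setdiff(names(counts), missing_level)
    known <- stats::setNames(as.numeric(counts[lv]), lv)
    if (sum(known) == 0) return(known * NA_real_)
    known / sum(known)
  }
  sex_counts <- table(factor(p$sex, levels = SEX_LEVELS))
  race_counts <- table(factor(p$race, levels = RACE_LEVELS))
  if (nrow(p)) {
    ages <- age_at(p$date_of_birth, as.Date(reference_date))
    age_by_sex <- do.call(rbind, lapply(c("male", "female"), function(s) {
      a <- ages[p$sex == s]
      if (!length(a))
        return(data.frame(sex = s, n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, iqr = NA_real_))
      q <- stats::quantile(a, c(.25, .75), type = 7, names = FALSE)
      data.frame(sex = s, n = length(a), median = stats::median(a),
                 q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
    }))
  } else {
    age_by_sex <- data.frame(sex = character(0), n = integer(0),
                             median = numeric(0), q1 = numeric(0),
                             q3 = numeric(0), iqr = numeric(0))
  }
  structure(list(n = nrow(p),
                 sex_counts = sex_counts, sex_props = prop_of(sex_counts, "unknown"),
                 race_counts = race_counts,
                 race_props = prop_of(race_counts, "unknown"),
                 age_by_sex = age_by_sex),
            class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("<demographics_summary: n = %d>\n", x$n))
  if (x$n > 0) {
    cat("  sex:", paste(sprintf("%s %.1f%%", names(x$sex_props),
                                100 * x$sex_props), collapse = ", "), "\n")
    cat("  race:", paste(sprintf("%s %.1f%%", names(x$race_props),
                                 100 * x$race_props), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-sample t-test for a difference in means
#'
#' Tests the null hypothesis that two groups (e.g. LDL-C in diagnosed
#' true-positive vs screen-suspect cohorts) share a mean. The Welch variant
#' (default) does not assume equal variances and uses the
#' Welch–Satterthwaite degrees of freedom; the pooled variant assumes a
#' common variance with `n_a + n_b - 2` df. Two-sided p-value.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 with
#'   nonzero variance.
#' @param variant `"welch"` or `"pooled"`.
#' @return A list of class `t_test_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_a`, `mean_b`, `variant`.
#' @export
two_sample_t_test <- function(values_a, values_b,
                              variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("two_sample_t_test: each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("two_sample_t_test: both groups have zero variance")
  ma <- mean(a); mb <- mean(b)
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_statistic = t_stat, degrees_of_freedom = df, p_value = p,
                 mean_a = ma, mean_b = mb, variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$variant, x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  means: %.4f vs %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Prevalence expressed as "1 in N"
#'
#' `N = cohort_size / n_cases`, rounded to the nearest multiple of
#' `round_to` (ties away from zero). E.g. 4 cases in 1,280,000 patients is
#' 1 in 320,000; 161 cases rounded to the nearest 1,000 is 1 in 8,000.
#'
#' @param n_cases Number of cases (>= 1).
#' @param cohort_size Denominator population (>= `n_cases`).
#' @param round_to Rounding granularity for N (default 1).
#' @return N as a number: prevalence is "1 in N".
#' @export
prevalence_one_in_n <- function(n_cases, cohort_size, round_to = 1) {
  if (n_cases < 1) stop("prevalence undefined for zero cases")
  if (cohort_size < n_cases) stop("cohort_size must be >= n_cases")
  round_half_away(cohort_size / n_cases / round_to) * round_to
}

#' Percentage increase over a baseline
#'
#' `100 * additional / baseline`; e.g. 2 newly flagged cases over a baseline
#' of 4 diagnosed cases is a 50% increase.
#'
#' @param additional Added count.
#' @param baseline Baseline count (> 0).
#' @return Percentage (50 means 50%).
#' @export
percent_increase <- function(additional, baseline) {
  if (baseline <= 0) stop("percent_increase: baseline must be positive")
  100 * additional / baseline
}

#' Expected case count at a population rate
#'
#' `cohort_size * rate_per_person`, rounded up (`"ceil"`, the conservative
#' "at least this many" reading) or to the nearest integer (`"nearest"`).
#' E.g. at an incidence of 1 in 100,000, a 1.28-million-patient cohort is
#' expected to hold at least 13 cases.
#'
#' @param cohort_size Population size.
#' @param rate_per_person Rate in (0, 1).
#' @param rounding `"ceil"` or `"nearest"`.
#' @return Expected number of cases (integer-valued).
#' @export
expected_cases <- function(cohort_size, rate_per_person,
                           rounding = c("ceil", "nearest")) {
  rounding <- match.arg(rounding)
  if (rate_per_person <= 0 || rate_per_person >= 1)
    stop("rate_per_person must be in (0, 1)")
  x <- cohort_size * rate_per_person
  if (rounding == "ceil") ceiling(x) else round_half_away(x)
}
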