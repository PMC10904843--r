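# Synthetic structured-EHR cohort generator. Plants known cases, suspects,
# near-miss decoys and negatives for both diseases, together with a
# ground-truth manifest, so the screens can be validated end to end with
# zero tolerance: by construction every planted archetype satisfies (or,
# for a near-miss, violates by exactly one clause) the corresponding rule.
#
# Distributional anchors: race mix 61% Chinese / 15.5% Malay / 11.7% Indian
# / 11.8% other; Fabry suspects ~60:40 male:female with median age just
# over 40; FH suspects ~42:58 male:female; suspect-adult LDL-C right-skewed
# and concentrated just above the 4.9 mmol/L flag level, with a rare
# extreme tail above 20 mmol/L.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 5,000-patient miniature of a multi-institution
#' extract: 4 Fabry known cases, 20 Fabry suspects, 16 FH known cases, 120
#' FH suspects, and 50 near-miss decoys, the remainder negatives.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @param window A `data_window`; every event date falls inside it.
#' @param race_probs Named numeric probabilities for chinese, malay, indian,
#'   other; must sum to 1.
#' @param fabry List: `n_known`, `n_suspect`, `suspect_male_frac`,
#'   `system_multiplicity` (probabilities over 2..5 affected systems).
#' @param fh List: `n_known`, `n_suspect`, `suspect_female_frac`,
#'   `known_male_frac`, `extreme_tail_prob` (chance an adult-rule suspect
#'   draws an extreme LDL-C in (20, 25) mmol/L), `rule_mix` (probabilities
#'   over adult/child/statin/ascvd planting rules).
#' @param n_near_miss Number of decoys, cycled over the four near-miss
#'   types: age-50-plus multisystem, under-50 single-system, LDL exactly at
#'   threshold, statin below the high-intensity dose.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 5000, seed = 1L,
                             window = data_window(),
                             race_probs = c(chinese = 0.61, malay = 0.155,
                                            indian = 0.117, other = 0.118),
                             fabry = list(), fh = list(), n_near_miss = 50) {
  fabry_def <- list(n_known = 4, n_suspect = 20, suspect_male_frac = 0.6,
                    system_multiplicity = c(`2` = 0.80, `3` = 0.15,
                                            `4` = 0.04, `5` = 0.01))
  fh_def <- list(n_known = 16, n_suspect = 120, suspect_female_frac = 0.58,
                 known_male_frac = 0.53, extreme_tail_prob = 0.01,
                 rule_mix = c(adult = 0.55, child = 0.15, statin = 0.15,
                              ascvd = 0.15))
  fabry <- utils::modifyList(fabry_def, fabry)
  fh <- utils::modifyList(fh_def, fh)
  if (abs(sum(race_probs) - 1) > 1e-9) stop("race_probs must sum to 1")
  if (any(race_probs < 0) || any(race_probs > 1))
    stop("race_probs must be probabilities")
  planted <- fabry$n_known + fabry$n_suspect + fh$n_known + fh$n_suspect +
    n_near_miss
  if (planted > n_patients)
    stop(sprintf("infeasible config: %d planted patients > n_patients = %d",
                 planted, n_patients))
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 window = window, race_probs = race_probs, fabry = fabry,
                 fh = fh, n_near_miss = n_near_miss),
            class = "synthetic_config")
}

# fixed-offset sub-streams: each generation stage reseeds from the base
# seed so adding draws to one stage does not perturb another
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + offset * 7919) %% 2147483647)
}

# triangular sampler (inverse CDF), used for suspect ages
rtriangular <- function(n, min, max, mode) {
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Sample synthetic LDL-C concentrations
#'
#' `"suspect_adult"` draws a shifted log-normal with support strictly above
#' 4.9 mmol/L, concentrated just over the flag level and right-skewed; with
#' probability `extreme_tail_prob` the draw is replaced by an extreme value
#' in (20, 25) mmol/L. `"suspect_child"` is the analogue above 3.9;
#' `"statin_range"` is uniform in (2.8, 3.8) (fires only the statin rule);
#' `"negative"` is uniform in (1.2, 2.5), below every threshold.
#'
#' @param n Number of draws.
#' @param archetype One of `"suspect_adult"`, `"suspect_child"`,
#'   `"statin_range"`, `"negative"`.
#' @param extreme_tail_prob Extreme-tail probability for the adult
#'   archetype.
#' @return Numeric vector, mmol/L.
#' @export
sample_ldl <- function(n, archetype = c("suspect_adult", "suspect_child",
                                        "statin_range", "negative"),
                       extreme_tail_prob = 0.01) {
  archetype <- match.arg(archetype)
  switch(archetype,
    suspect_adult = {
      # the 0.01 floor keeps 3-decimal serialisation strictly above 4.9
      v <- 4.9 + pmax(stats::rlnorm(n, meanlog = log(0.35), sdlog = 0.8), 0.01)
      tail <- stats::runif(n) < extreme_tail_prob
      v[tail] <- stats::runif(sum(tail), 20.5, 24.5)
      v
    },
    suspect_child = 3.9 + pmax(stats::rlnorm(n, meanlog = log(0.3), sdlog = 0.6),
                               0.01),
    statin_range = stats::runif(n, 2.8, 3.8),
    negative = stats::runif(n, 1.2, 2.5)
  )
}

# dob such that completed age at `ref` lies in [lo, hi]; days bounds chosen
# so integer truncation can never leave the band
sample_dob <- function(n, ref, lo, hi, mode = NULL) {
  dmin <- ceiling(lo * 366)
  dmax <- floor((hi + 1) * 365) - 1
  days <- if (is.null(mode)) {
    stats::runif(n, dmin, dmax)
  } else {
    rtriangular(n, dmin, dmax, mode * 365.25)
  }
  ref - floor(days)
}

rand_dates <- function(n, window) {
  span <- as.integer(window$end - window$start)
  window$start + floor(stats::runif(n, 0, span + 1 - 1e-9))
}

# decoy problem descriptions guaranteed not to match any default value set
BENIGN_PROBLEMS <- c("type 2 diabetes mellitus", "essential hypertension",
                     "asthma", "upper respiratory tract infection",
                     "gastro-oesophageal reflux disease", "osteoarthritis",
                     "allergic rhinitis", "migraine without aura")

# One representative phenotype description per (system, value set).
# Descriptions shared with the ASCVD value set (ischaemic stroke) are
# excluded so a planted Fabry phenotype can never cross-trigger the FH
# premature-ASCVD rule: the truth manifest assigns one archetype per
# patient and must stay single-labelled.
system_phenotype_pool <- function(system_map, catalog) {
  ascvd_syn <- if ("ascvd" %in% names(catalog$sets))
    catalog$sets[["ascvd"]]$synonyms else character(0)
  lapply(system_map, function(sets)
    unlist(lapply(sets, function(s) {
      syn <- setdiff(catalog$sets[[s]]$synonyms, ascvd_syn)
      if (length(syn)) syn[1] else NULL
    })))
}

#' Generate a synthetic EHR cohort with ground truth
#'
#' Produces the four EHR tables plus a `truth` manifest mapping every
#' patient to its planted archetype. Deterministic given the config
#' (including seed): repeated calls yield byte-identical CSVs through
#' [write_cohort()].
#'
#' Planting guarantees, by construction: every `fabry_suspect` is under 50
#' at the window end with phenotypes in >= 2 systems; every `fh_suspect`
#' satisfies exactly its planted rule family; every `near_miss_*` fails its
#' designated clause and only that clause; `*_known` patients carry the
#' disease diagnosis code (half of Fabry known cases additionally carry
#' suspect-like evidence, exercising preemption); negatives match nothing.
#'
#' @param config A `synthetic_config`.
#' @param catalog Catalog used to source phenotype descriptions (defaults
#'   to [default_catalog()]).
#' @param system_map See [default_system_map()].
#' @return A list of class `synthetic_cohort`: `cohort` (an `ehr_cohort`),
#'   `truth` (data frame `patient_id`, `archetype`, `detail`), `config`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            catalog = default_catalog(),
                            system_map = default_system_map()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  win <- config$window
  fab <- config$fabry
  fh <- config$fh
  old <- local_seed(derive_seed(config$seed, 1))
  on.exit(restore_seed(old), add = TRUE)

  ids <- sprintf("PID%06d", seq_len(n))

  # archetype layout, then a seeded shuffle so planted cases are scattered
  nm_types <- rep_len(c("near_miss_fabry_age", "near_miss_fabry_single_system",
                        "near_miss_fh_ldl_at_threshold",
                        "near_miss_fh_low_intensity_statin"),
                      config$n_near_miss)
  arch <- c(rep("fabry_known", fab$n_known), rep("fabry_suspect", fab$n_suspect),
            rep("fh_known", fh$n_known), rep("fh_suspect", fh$n_suspect),
            nm_types,
            rep("negative", n - fab$n_known - fab$n_suspect - fh$n_known -
                  fh$n_suspect - config$n_near_miss))
  arch <- arch[sample.int(n)]

  race <- names(config$race_probs)[
    sample.int(length(config$race_probs), n, replace = TRUE,
               prob = config$race_probs)]

  sex <- character(n)
  dob <- rep(win$end, n)
  detail <- character(n)

  # columnar collectors: appending one row at a time to lists of scalars is
  # fast enough at this scale, where rbind-ing thousands of one-row data
  # frames is not
  pc <- new.env(parent = emptyenv())
  pc$rows <- list()
  lc <- new.env(parent = emptyenv())
  lc$rows <- list()
  mc <- new.env(parent = emptyenv())
  mc$rows <- list()
  add_problem <- function(id, desc, date, code = "X-UNCODED",
                          code_system = "local") {
    pc$rows[[length(pc$rows) + 1]] <-
      c(id, code, code_system, desc, as.character(date))
  }
  add_lab <- function(id, value, date) {
    lc$rows[[length(lc$rows) + 1]] <-
      c(id, "LDL_C", as.character(round(value, 3)), "mmol/L",
        as.character(date))
  }
  add_med <- function(id, drug, dose, start, end) {
    mc$rows[[length(mc$rows) + 1]] <-
      c(id, drug, as.character(dose), as.character(start),
        if (is.na(end)) "" else as.character(end))
  }
  plant_systems <- function(id, k, date_pool) {
    pool <- system_phenotype_pool(system_map, catalog)
    systems <- sample(SYSTEMS, k)
    for (s in systems) {
      descs <- pool[[s]]
      # occasionally plant two phenotypes of the same system to exercise
      # within-system deduplication, plus case/space jitter on descriptions
      take <- if (stats::runif(1) < 0.3) min(2, length(descs)) else 1
      for (d in sample(descs, take)) {
        jit <- if (stats::runif(1) < 0.5) toupper(d) else d
        add_problem(id, jit, sample(date_pool, 1))
      }
    }
    systems
  }
  statin_order <- function(id, draw, high_intensity = TRUE) {
    pick <- sample(1:2, 1)
    drug <- c("atorvastatin", "rosuvastatin")[pick]
    dose <- if (high_intensity) c(40, 20)[pick] * sample(1:2, 1)
            else c(10, 5)[pick]
    start <- max(win$start, draw - sample(30:200, 1))
    end <- if (stats::runif(1) < 0.3) as.Date(NA)
           else min(win$end, draw + sample(30:200, 1))
    add_med(id, drug, dose, start, end)
  }

  set.seed(derive_seed(config$seed, 2))
  for (i in seq_len(n)) {
    id <- ids[i]
    a <- arch[i]
    dates <- rand_dates(8, win)
    if (a == "fabry_known") {
      sex[i] <- if (stats::runif(1) < 0.6) "male" else "female"
      dob[i] <- sample_dob(1, win$end, 10, 69)
      add_problem(id, "Fabry disease", dates[1], code = "LC-FABRY-DISEASE")
      if (stats::runif(1) < 0.5) {  # preemption: known + suspect-like evidence
        dob[i] <- sample_dob(1, win$end, 20, 48)
        plant_systems(id, 2, dates[-1])
        detail[i] <- "dx+evidence"
      } else detail[i] <- "dx_only"
    } else if (a == "fabry_suspect") {
      sex[i] <- if (stats::runif(1) < fab$suspect_male_frac) "male" else "female"
      dob[i] <- sample_dob(1, win$end, 18, 49, mode = 41)
      k <- as.integer(names(fab$system_multiplicity))[
        sample.int(length(fab$system_multiplicity), 1,
                   prob = fab$system_multiplicity)]
      sys <- plant_systems(id, k, dates)
      detail[i] <- paste(sort(sys), collapse = "+")
    } else if (a == "fh_known") {
      sex[i] <- if (stats::runif(1) < fh$known_male_frac) "male" else "female"
      dob[i] <- sample_dob(1, win$end, 25, 70)
      use_code <- stats::runif(1) < 0.5
      add_problem(id, if (use_code) "hyperlipidaemia review"
                      else "Familial Hypercholesterolaemia", dates[1],
                  code = if (use_code) "398036000" else "X-UNCODED",
                  code_system = if (use_code) "SNOMED" else "local")
      add_lab(id, sample_ldl(1, "suspect_adult", fh$extreme_tail_prob), dates[2])
      detail[i] <- if (use_code) "dx_code" else "dx_synonym"
    } else if (a == "fh_suspect") {
      rule <- names(fh$rule_mix)[sample.int(length(fh$rule_mix), 1,
                                            prob = fh$rule_mix)]
      sex[i] <- if (stats::runif(1) < fh$suspect_female_frac) "female" else "male"
      if (rule == "adult") {
        dob[i] <- sample_dob(1, win$end, 24, 75)
        add_lab(id, sample_ldl(1, "suspect_adult", fh$extreme_tail_prob), dates[1])
      } else if (rule == "child") {
        dob[i] <- sample_dob(1, win$end, 10, 17)
        add_lab(id, sample_ldl(1, "suspect_child"), dates[1])
      } else if (rule == "statin") {
        dob[i] <- sample_dob(1, win$end, 24, 75)
        add_lab(id, sample_ldl(1, "statin_range"), dates[1])
        statin_order(id, dates[1], high_intensity = TRUE)
      } else {  # ascvd
        hi <- if (sex[i] == "male") 49 else 54  # event age stays premature
        dob[i] <- sample_dob(1, win$end, 30, hi)
        add_problem(id, sample(c("myocardial infarction", "angina"), 1),
                    dates[1],
                    code = if (stats::runif(1) < 0.5) "LC-ASCVD" else "X-UNCODED")
      }
      detail[i] <- rule
    } else if (a == "near_miss_fabry_age") {
      sex[i] <- if (stats::runif(1) < 0.5) "male" else "female"
      # half sit exactly on the age-50 boundary (birthday on window end)
      dob[i] <- if (stats::runif(1) < 0.5)
        as.Date(sprintf("%d-%s", as.integer(format(win$end, "%Y")) - 50,
                        format(win$end, "%m-%d")))
      else sample_dob(1, win$end, 51, 80)
      sys <- plant_systems(id, sample(2:3, 1), dates)
      detail[i] <- paste0("age", age_at(dob[i], win$end))
    } else if (a == "near_miss_fabry_single_system") {
      sex[i] <- if (stats::runif(1) < 0.5) "male" else "female"
      dob[i] <- sample_dob(1, win$end, 20, 48)
      sys <- plant_systems(id, 1, dates)
      detail[i] <- sys[1]
    } else if (a == "near_miss_fh_ldl_at_threshold") {
      sex[i] <- if (stats::runif(1) < 0.5) "male" else "female"
      child <- stats::runif(1) < 0.3
      if (child) {
        dob[i] <- sample_dob(1, win$end, 10, 17)
        add_lab(id, 3.9, dates[1])  # strict > fails at exactly 3.9
      } else {
        dob[i] <- sample_dob(1, win$end, 24, 75)
        add_lab(id, 4.9, dates[1])  # strict > fails at exactly 4.9
      }
      detail[i] <- if (child) "child3.9" else "adult4.9"
    } else if (a == "near_miss_fh_low_intensity_statin") {
      sex[i] <- if (stats::runif(1) < 0.5) "male" else "female"
      dob[i] <- sample_dob(1, win$end, 24, 75)
      add_lab(id, stats::runif(1, 3.0, 3.8), dates[1])
      statin_order(id, dates[1], high_intensity = FALSE)
      detail[i] <- "sub_dose"
    } else {  # negative
      sex[i] <- if (stats::runif(1) < 0.5) "male" else "female"
      has_lab <- stats::runif(1) < 0.3
      # lab-bearing patients must be born before the window opens so every
      # draw date postdates birth
      dob[i] <- sample_dob(1, win$end, if (has_lab) 6 else 1, 89)
      for (j in seq_len(sample(0:3, 1)))
        add_problem(id, sample(BENIGN_PROBLEMS, 1), dates[j])
      if (has_lab) add_lab(id, sample_ldl(1, "negative"), dates[4])
      if (stats::runif(1) < 0.05) statin_order(id, dates[4], high_intensity = FALSE)
      detail[i] <- ""
    }
  }

  col <- function(rows, j, names) {
    m <- if (length(rows)) do.call(rbind, rows) else
      matrix(character(0), ncol = length(names))
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- names
    out
  }
  patients <- data.frame(patient_id = ids, sex = sex, race = race,
                         date_of_birth = as.character(dob),
                         stringsAsFactors = FALSE)
  cohort <- as_ehr_cohort(
    patients,
    col(pc$rows, 5, c("patient_id", "code", "code_system", "description",
                      "entry_date")),
    col(lc$rows, 5, c("patient_id", "analyte", "value", "units", "draw_date")),
    col(mc$rows, 5, c("patient_id", "drug_name", "dose_mg", "start_date",
                      "end_date")))
  if (nrow(cohort$rejects) > 0)
    stop("internal error: generator produced invalid rows")
  truth <- data.frame(patient_id = ids, archetype = arch, detail = detail,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients (seed %d)>\n",
              nrow(x$cohort$patients), x$config$seed))
  print(table(x$truth$archetype))
  invisible(x)
}

#' Write a synthetic cohort including its truth manifest
#'
#' Writes the four EHR tables via [write_cohort()] plus `truth.csv`.
#'
#' @param sc A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_cohort <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  paths <- write_cohort(sc$cohort, dir)
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(sc$truth, tp, row.names = FALSE, quote = TRUE)
  invisible(c(paths, tp))
}

# expected screen statuses implied by the manifest; the acceptance surface
# for screen-recovery tests
truth_expectations <- function(truth) {
  fabry <- ifelse(truth$archetype == "fabry_known", "known_case",
           ifelse(truth$archetype == "fabry_suspect", "suspect", "negative"))
  fh <- ifelse(truth$archetype == "fh_known", "known_case",
        ifelse(truth$archetype == "fh_suspect", "suspect", "negative"))
  data.frame(patient_id = truth$patient_id, fabry_expected = fabry,
             fh_expected = fh, stringsAsFactors = FALSE)
}
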