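# Familial-hypercholesterolaemia case-finding rule: a suspect satisfies ANY
# of five clauses — premature ASCVD (male < 55 / female < 60 at earliest
# qualifying event), LDL-C > 2.6 mmol/L while adhering to a high-intensity
# statin, LDL-C > 3.9 mmol/L at age <= 18, or LDL-C > 4.9 mmol/L at age
# > 18. All thresholds are strict; ages for lab clauses use the draw date.
# A coded FH diagnosis preempts suspect status.

FH_RULES <- c("ascvd_male_lt55", "ascvd_female_lt60", "ldl_statin_gt2.6",
              "ldl_child_gt3.9", "ldl_adult_gt4.9")

#' FH screening rule thresholds
#'
#' Defaults follow the screening criteria: ASCVD age cutoffs 55 (male) / 60
#' (female); LDL-C 2.6 mmol/L on a high-intensity statin; 3.9 mmol/L at age
#' 18 or younger; 4.9 mmol/L over 18. "Adhering to high-intensity statins"
#' is operationalised as an active order at or above the class-defining dose
#' (atorvastatin >= 40 mg, rosuvastatin >= 20 mg) covering the draw date —
#' a proxy, since structured orders carry no dispensing granularity.
#'
#' @param ascvd_age_male,ascvd_age_female Strict age cutoffs (years) for
#'   premature ASCVD.
#' @param ldl_on_statin,ldl_child,ldl_adult Strict LDL-C thresholds, mmol/L.
#' @param child_age_max Inclusive upper age for the child rule; a patient
#'   aged exactly this is evaluated only by the child rule.
#' @param high_intensity_statins Data frame (`drug_name`, `min_dose_mg`).
#' @return A list of class `fh_rules`.
#' @export
fh_rules <- function(ascvd_age_male = 55, ascvd_age_female = 60,
                     ldl_on_statin = 2.6, ldl_child = 3.9, ldl_adult = 4.9,
                     child_age_max = 18,
                     high_intensity_statins = data.frame(
                       drug_name = c("atorvastatin", "rosuvastatin"),
                       min_dose_mg = c(40, 20),
                       stringsAsFactors = FALSE)) {
  thr <- c(ldl_on_statin, ldl_child, ldl_adult)
  if (any(thr <= 0) || ascvd_age_male <= 0 || ascvd_age_female <= 0)
    stop("fh_rules: thresholds must be positive")
  if (is.unsorted(thr, strictly = TRUE))
    warning("fh_rules: LDL thresholds do not satisfy statin < child < adult ordering")
  structure(list(ascvd_age_male = ascvd_age_male,
                 ascvd_age_female = ascvd_age_female,
                 ldl_on_statin = ldl_on_statin, ldl_child = ldl_child,
                 ldl_adult = ldl_adult, child_age_max = child_age_max,
                 high_intensity_statins = high_intensity_statins),
            class = "fh_rules")
}

#' Premature ASCVD check for one patient
#'
#' True iff the problem list contains an ASCVD-value-set match and the
#' patient's completed age at the EARLIEST matching entry date is strictly
#' below the sex-specific cutoff. Prematurity is an onset property, so the
#' event date — not the window end — anchors the age. Patients of unknown
#' sex are not evaluable by this rule.
#'
#' @param patient One-row patients data frame or list.
#' @param problems The patient's problem entries.
#' @param catalog A `value_set_catalog`.
#' @param ascvd_set Name of the ASCVD value set.
#' @param rules An `fh_rules` object.
#' @param window A `data_window`; entries outside it are ignored when
#'   `window_filter` is `TRUE`.
#' @param window_filter Logical.
#' @return List with `premature` (logical) and `rule`
#'   (`"ascvd_male_lt55"`, `"ascvd_female_lt60"`, or `NA`).
#' @export
is_premature_ascvd <- function(patient, problems, catalog = default_catalog(),
                               ascvd_set = "ascvd", rules = fh_rules(),
                               window = data_window(), window_filter = TRUE) {
  sex <- as.character(patient$sex)
  if (!sex %in% c("male", "female")) {
    message("is_premature_ascvd: sex unknown, rule not applicable for ",
            patient$patient_id)
    return(list(premature = FALSE, rule = NA_character_))
  }
  if (window_filter && nrow(problems))
    problems <- problems[problems$entry_date >= window$start &
                         problems$entry_date <= window$end, , drop = FALSE]
  mp <- match_problems(problems, catalog)
  rows <- mp$row[mp$set == ascvd_set]
  if (!length(rows)) return(list(premature = FALSE, rule = NA_character_))
  first <- min(problems$entry_date[rows])
  age <- age_at(as.Date(patient$date_of_birth), first)
  cutoff <- if (sex == "male") rules$ascvd_age_male else rules$ascvd_age_female
  if (age < cutoff)
    list(premature = TRUE,
         rule = if (sex == "male") "ascvd_male_lt55" else "ascvd_female_lt60")
  else list(premature = FALSE, rule = NA_character_)
}

#' Is a high-intensity statin order active on a date?
#'
#' True iff at least one order names a drug on the high-intensity list at or
#' above its minimum dose and its `[start_date, end_date]` interval covers
#' `date`. A missing end date means the order is open — active through the
#' window end and beyond.
#'
#' @param meds Medication-order data frame.
#' @param date The date to test (e.g. an LDL-C draw date).
#' @param rules An `fh_rules` object.
#' @return Logical scalar.
#' @export
on_high_intensity_statin <- function(meds, date, rules = fh_rules()) {
  if (nrow(meds) == 0) return(FALSE)
  date <- as.Date(date)
  his <- rules$high_intensity_statins
  i <- match(tolower(meds$drug_name), tolower(his$drug_name))
  qual <- !is.na(i) & meds$dose_mg >= his$min_dose_mg[i]
  covers <- meds$start_date <= date & (is.na(meds$end_date) | meds$end_date >= date)
  any(qual & covers)
}

#' Screen a full cohort for FH suspects
#'
#' Evaluates every clause over every in-window LDL-C result and the problem
#' list, per patient. Status is `known_case` if the FH diagnosis value set
#' matches (preempting suspect), `suspect` iff any rule fires, else
#' `negative`. `qualifying_ldl` is the maximum LDL-C among rule-firing
#' results (`NA` for ASCVD-only suspects).
#'
#' @param cohort An `ehr_cohort` (LDL-C already in mmol/L — [read_cohort()]
#'   normalises units).
#' @param catalog A `value_set_catalog`.
#' @param rules An `fh_rules` object.
#' @param fh_set,ascvd_set Value-set names for the FH diagnosis and ASCVD
#'   events.
#' @param window A `data_window`.
#' @param window_filter Restrict problems and labs to the window (default
#'   `TRUE`).
#' @return A list of class `fh_screen`: `results` (data frame with
#'   `patient_id`, `status`, `triggered_rules` semicolon-joined,
#'   `qualifying_ldl`), `n_known`, `n_suspect`.
#' @export
screen_fh_cohort <- function(cohort, catalog = default_catalog(),
                             rules = fh_rules(),
                             fh_set = "familial_hypercholesterolaemia",
                             ascvd_set = "ascvd",
                             window = data_window(), window_filter = TRUE) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(rules, "fh_rules"))
  for (s in c(fh_set, ascvd_set))
    if (!s %in% names(catalog$sets)) stop("unknown value set: ", s)
  pat <- cohort$patients
  problems <- cohort$problems
  labs <- cohort$labs
  if (window_filter) {
    if (nrow(problems))
      problems <- problems[problems$entry_date >= window$start &
                           problems$entry_date <= window$end, , drop = FALSE]
    if (nrow(labs))
      labs <- labs[labs$draw_date >= window$start &
                   labs$draw_date <= window$end, , drop = FALSE]
  }
  labs <- labs[labs$analyte == "LDL_C", , drop = FALSE]

  mp <- match_problems(problems, catalog)
  known_ids <- unique(problems$patient_id[mp$row[mp$set == fh_set]])

  fired <- list()  # each: data.frame(patient_id, rule, ldl)

  # premature ASCVD: earliest qualifying event per patient
  arows <- mp$row[mp$set == ascvd_set]
  if (length(arows)) {
    ev <- problems[arows, c("patient_id", "entry_date")]
    first <- stats::aggregate(entry_date ~ patient_id, data = ev, FUN = min)
    j <- match(first$patient_id, pat$patient_id)
    sex <- pat$sex[j]
    age <- age_at(pat$date_of_birth[j], first$entry_date)
    hit_m <- sex == "male" & age < rules$ascvd_age_male
    hit_f <- sex == "female" & age < rules$ascvd_age_female
    if (any(hit_m))
      fired$am <- data.frame(patient_id = first$patient_id[hit_m],
                             rule = "ascvd_male_lt55", ldl = NA_real_)
    if (any(hit_f))
      fired$af <- data.frame(patient_id = first$patient_id[hit_f],
                             rule = "ascvd_female_lt60", ldl = NA_real_)
  }

  if (nrow(labs)) {
    dob <- pat$date_of_birth[match(labs$patient_id, pat$patient_id)]
    lab_age <- age_at(dob, labs$draw_date)

    # statin coverage per lab row, via a patient-keyed join against the
    # qualifying (high-intensity, dose-sufficient) orders only
    his <- rules$high_intensity_statins
    meds <- cohort$meds
    mi <- match(tolower(meds$drug_name), tolower(his$drug_name))
    qual <- meds[!is.na(mi) & meds$dose_mg >= his$min_dose_mg[mi], , drop = FALSE]
    covered <- rep(FALSE, nrow(labs))
    if (nrow(qual)) {
      lr <- data.frame(lab = seq_len(nrow(labs)), patient_id = labs$patient_id,
                       draw = labs$draw_date, stringsAsFactors = FALSE)
      jn <- merge(lr, qual[, c("patient_id", "start_date", "end_date")],
                  by = "patient_id")
      ok <- jn$start_date <= jn$draw & (is.na(jn$end_date) | jn$end_date >= jn$draw)
      covered[unique(jn$lab[ok])] <- TRUE
    }

    child <- labs$value > rules$ldl_child & lab_age <= rules$child_age_max
    adult <- labs$value > rules$ldl_adult & lab_age > rules$child_age_max
    statin <- labs$value > rules$ldl_on_statin & covered
    if (any(statin))
      fired$ls <- data.frame(patient_id = labs$patient_id[statin],
                             rule = "ldl_statin_gt2.6", ldl = labs$value[statin])
    if (any(child))
      fired$lc <- data.frame(patient_id = labs$patient_id[child],
                             rule = "ldl_child_gt3.9", ldl = labs$value[child])
    if (any(adult))
      fired$la <- data.frame(patient_id = labs$patient_id[adult],
                             rule = "ldl_adult_gt4.9", ldl = labs$value[adult])
  }

  hits <- do.call(rbind, c(list(data.frame(patient_id = character(0),
                                           rule = character(0), ldl = numeric(0))),
                           unname(fired)))
  rules_by_pat <- lapply(split(hits$rule, hits$patient_id),
                         function(r) FH_RULES[FH_RULES %in% r])
  ldl_by_pat <- vapply(split(hits$ldl, hits$patient_id),
                       function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                       numeric(1))

  status <- rep("negative", nrow(pat))
  status[pat$patient_id %in% hits$patient_id] <- "suspect"
  status[pat$patient_id %in% known_ids] <- "known_case"

  trig <- character(nrow(pat))
  i <- match(pat$patient_id, names(rules_by_pat))
  trig[!is.na(i)] <- vapply(rules_by_pat[i[!is.na(i)]], paste, character(1),
                            collapse = ";")
  trig[status == "known_case"] <- ""
  qldl <- rep(NA_real_, nrow(pat))
  qldl[!is.na(i)] <- ldl_by_pat[i[!is.na(i)]]
  qldl[status == "known_case"] <- NA_real_

  results <- data.frame(patient_id = pat$patient_id, status = status,
                        triggered_rules = trig, qualifying_ldl = qldl,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = results,
                 n_known = sum(status == "known_case"),
                 n_suspect = sum(status == "suspect")),
            class = "fh_screen")
}

#' @export
print.fh_screen <- function(x, ...) {
  cat(sprintf("<fh_screen: %d patients, %d known case(s), %d suspect(s)>\n",
              nrow(x$results), x$n_known, x$n_suspect))
  invisible(x)
}

#' Screen a single patient for FH
#'
#' Single-patient form of [screen_fh_cohort()].
#'
#' @param patient One-row patients data frame or list.
#' @param problems,labs,meds The patient's rows of each table.
#' @inheritParams screen_fh_cohort
#' @return A list with `patient_id`, `status`, `triggered_rules` (character
#'   vector), `qualifying_ldl`.
#' @export
flag_fh <- function(patient, problems, labs, meds,
                    catalog = default_catalog(), rules = fh_rules(),
                    fh_set = "familial_hypercholesterolaemia",
                    ascvd_set = "ascvd", window = data_window(),
                    window_filter = TRUE) {
  pat <- as.data.frame(patient, stringsAsFactors = FALSE)
  cohort <- as_ehr_cohort(pat, problems, labs, meds)
  scr <- screen_fh_cohort(cohort, catalog, rules, fh_set, ascvd_set, window,
                          window_filter)
  r <- scr$results[1, ]
  list(patient_id = r$patient_id, status = r$status,
       triggered_rules = if (nzchar(r$triggered_rules))
         strsplit(r$triggered_rules, ";", fixed = TRUE)[[1]] else character(0),
       qualifying_ldl = r$qualifying_ldl)
}
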