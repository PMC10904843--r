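# Fabry-disease case-finding rule: a suspect is a patient less than 50 years
# old with phenotypes in at least two of five organ systems (kidney,
# cardiac, neuro, skin, eye). A coded Fabry diagnosis makes the patient a
# known case, which preempts suspect status so known and suspect cohorts are
# disjoint.

SYSTEMS <- c("kidney", "cardiac", "neuro", "skin", "eye")

#' Default organ-system to value-set map
#'
#' Maps each of the five Fabry organ systems to the phenotype value sets
#' that define it: kidney (chronic kidney disease, proteinuria,
#' microalbuminuria), cardiac (cardiomyopathy, valvular heart disease,
#' arrhythmia), neuro (ischaemic stroke, transient ischaemic attack,
#' acroparaesthesia), skin (angiokeratomas, hypohidrosis, heat/cold
#' intolerance), eye (corneal whirling, cornea verticillata,
#' corneal/lenticular opacities, retinal/conjunctival vasculopathy).
#'
#' @return Named list, one character vector of value-set names per system.
#' @export
default_system_map <- function() {
  list(
    kidney = c("chronic_kidney_disease", "proteinuria", "microalbuminuria"),
    cardiac = c("cardiomyopathy", "valvular_heart_disease", "arrhythmia"),
    neuro = c("stroke_ischemic", "transient_ischemic_attack", "acroparaesthesia"),
    skin = c("angiokeratomas", "hypohidrosis", "heat_cold_intolerance"),
    eye = c("corneal_whirling", "cornea_verticillata",
            "corneal_lenticular_opacities", "retinal_vasculopathy")
  )
}

validate_system_map <- function(system_map, catalog) {
  if (!setequal(names(system_map), SYSTEMS))
    stop("system map must define exactly the five systems: ",
         paste(SYSTEMS, collapse = ", "))
  missing <- setdiff(unlist(system_map), names(catalog$sets))
  if (length(missing))
    stop("system map references unknown value set(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# set name -> system lookup (a set may in principle serve several systems)
invert_system_map <- function(system_map) {
  data.frame(set = unlist(system_map, use.names = FALSE),
             system = rep(names(system_map), lengths(system_map)),
             stringsAsFactors = FALSE)
}

#' Organ systems affected by a problem list
#'
#' A system is affected iff at least one problem entry matches at least one
#' of its value sets; entry multiplicity is irrelevant.
#'
#' @param problems Problem-entry data frame (any subset of a cohort's
#'   `problems` table).
#' @param system_map Named list, see [default_system_map()].
#' @param catalog A `value_set_catalog`.
#' @return Character vector of affected systems, in canonical order.
#' @export
assign_systems <- function(problems, system_map = default_system_map(),
                           catalog = default_catalog()) {
  validate_system_map(system_map, catalog)
  mp <- match_problems(problems, catalog)
  sys <- merge(mp, invert_system_map(system_map), by = "set")$system
  SYSTEMS[SYSTEMS %in% sys]
}

# cohort-wide: unique (patient_id, system) pairs
patient_system_pairs <- function(problems, system_map, catalog) {
  mp <- match_problems(problems, catalog)
  if (nrow(mp) == 0)
    return(data.frame(patient_id = character(0), system = character(0),
                      stringsAsFactors = FALSE))
  mp$patient_id <- problems$patient_id[mp$row]
  hit <- merge(mp, invert_system_map(system_map), by = "set")
  unique(hit[, c("patient_id", "system")])
}

#' Convert system pairs to a per-patient system-set list
#'
#' @param patients Patients data frame (defines the id universe).
#' @param pairs Data frame of (`patient_id`, `system`) pairs.
#' @return Named list mapping every patient id to a (possibly empty)
#'   character vector of systems in canonical order.
#' @keywords internal
systems_as_list <- function(patients, pairs) {
  out <- stats::setNames(vector("list", nrow(patients)), patients$patient_id)
  for (id in names(out)) out[[id]] <- character(0)
  if (nrow(pairs)) {
    sp <- split(pairs$system, pairs$patient_id)
    for (id in names(sp)) out[[id]] <- SYSTEMS[SYSTEMS %in% sp[[id]]]
  }
  out
}

#' Screen a full cohort for Fabry suspects
#'
#' Applies the rule to every patient: `known_case` if any problem entry
#' matches the Fabry diagnosis value set; otherwise `suspect` iff completed
#' age at the reference date is strictly less than 50 and at least two organ
#' systems are affected; otherwise `negative`.
#'
#' @param cohort An `ehr_cohort`.
#' @param catalog A `value_set_catalog`.
#' @param system_map See [default_system_map()].
#' @param fabry_set Name of the diagnosis value set in `catalog`.
#' @param window A `data_window`; when `window_filter` is `TRUE` only
#'   problem entries dated inside it are considered.
#' @param age_reference `"window_end"` (default: one age per patient, at the
#'   window end) or `"per_event"` (systems count only phenotype entries
#'   recorded before the patient turned 50).
#' @param window_filter Restrict problem entries to the window (default
#'   `TRUE`).
#' @return A list of class `fabry_screen`: `results` (data frame with
#'   `patient_id`, `status`, `affected_systems` semicolon-joined,
#'   `age_at_reference`), `systems` (named list per patient), `n_known`,
#'   `n_suspect`.
#' @export
screen_fabry_cohort <- function(cohort,
                                catalog = default_catalog(),
                                system_map = default_system_map(),
                                fabry_set = "fabry_disease",
                                window = data_window(),
                                age_reference = c("window_end", "per_event"),
                                window_filter = TRUE) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  age_reference <- match.arg(age_reference)
  validate_system_map(system_map, catalog)
  if (!fabry_set %in% names(catalog$sets))
    stop("unknown Fabry diagnosis value set: ", fabry_set)
  pat <- cohort$patients
  problems <- cohort$problems
  if (window_filter && nrow(problems))
    problems <- problems[problems$entry_date >= window$start &
                         problems$entry_date <= window$end, , drop = FALSE]

  ages <- if (nrow(pat)) age_at(pat$date_of_birth, window$end) else integer(0)

  mp <- match_problems(problems, catalog)
  known_ids <- unique(problems$patient_id[mp$row[mp$set == fabry_set]])

  if (age_reference == "per_event" && nrow(problems)) {
    dob <- pat$date_of_birth[match(problems$patient_id, pat$patient_id)]
    problems <- problems[age_at(dob, problems$entry_date) < 50, , drop = FALSE]
  }
  pairs <- patient_system_pairs(problems, system_map, catalog)
  nsys <- table(factor(pairs$patient_id, levels = pat$patient_id))
  nsys <- as.integer(nsys[pat$patient_id])

  status <- rep("negative", nrow(pat))
  status[ages < 50 & nsys >= 2] <- "suspect"
  status[pat$patient_id %in% known_ids] <- "known_case"

  sys_list <- systems_as_list(pat, pairs)
  results <- data.frame(
    patient_id = pat$patient_id,
    status = status,
    affected_systems = vapply(sys_list, paste, character(1), collapse = ";"),
    age_at_reference = ages,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = results, systems = sys_list,
                 n_known = sum(status == "known_case"),
                 n_suspect = sum(status == "suspect")),
            class = "fabry_screen")
}

#' @export
print.fabry_screen <- function(x, ...) {
  cat(sprintf("<fabry_screen: %d patients, %d known case(s), %d suspect(s)>\n",
              nrow(x$results), x$n_known, x$n_suspect))
  invisible(x)
}

#' Screen a single patient for Fabry disease
#'
#' Single-patient form of [screen_fabry_cohort()].
#'
#' @param patient One-row patients data frame (or list with `patient_id`,
#'   `sex`, `race`, `date_of_birth`).
#' @param problems The patient's problem entries.
#' @inheritParams screen_fabry_cohort
#' @return A list with `patient_id`, `status`, `affected_systems` (character
#'   vector), `age_at_reference`.
#' @export
flag_fabry <- function(patient, problems,
                       catalog = default_catalog(),
                       system_map = default_system_map(),
                       fabry_set = "fabry_disease",
                       window = data_window(),
                       age_reference = c("window_end", "per_event"),
                       window_filter = TRUE) {
  pat <- as.data.frame(patient, stringsAsFactors = FALSE)
  cohort <- as_ehr_cohort(pat, problems,
                          labs = data.frame(patient_id = character(0),
                                            analyte = character(0), value = numeric(0),
                                            units = character(0), draw_date = character(0)),
                          meds = data.frame(patient_id = character(0),
                                            drug_name = character(0), dose_mg = numeric(0),
                                            start_date = character(0), end_date = character(0)))
  scr <- screen_fabry_cohort(cohort, catalog, system_map, fabry_set, window,
                             age_reference, window_filter)
  list(patient_id = scr$results$patient_id[1],
       status = scr$results$status[1],
       affected_systems = scr$systems[[1]],
       age_at_reference = scr$results$age_at_reference[1])
}
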