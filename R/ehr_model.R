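# Domain model for the four structured-EHR tables: patients, problem-list
# entries, laboratory results and medication orders. All dates are day-level
# ISO-8601 calendar dates; LDL-C is carried in mmol/L after unit
# normalisation (mg/dL inputs are divided by 38.67).

SEX_LEVELS <- c("male", "female", "unknown")
RACE_LEVELS <- c("chinese", "malay", "indian", "other", "unknown")
CODE_SYSTEMS <- c("SNOMED", "local")
ANALYTES <- c("LDL_C", "other")

MG_DL_PER_MMOL_L <- 38.67

#' Observation window for a cohort extract
#'
#' A pair of calendar dates bounding the data extract. The default mirrors a
#' multi-institution hospital-cluster extract spanning 1 Jan 2018 to
#' 1 Mar 2022.
#'
#' @param start,end `Date` or ISO-8601 string; `start` must precede `end`.
#' @return An object of class `data_window` with elements `start` and `end`.
#' @export
#' @examples
#' data_window("2018-01-01", "2022-03-01")
data_window <- function(start = "2018-01-01", end = "2022-03-01") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window dates must be valid ISO-8601 dates")
  if (!(start < end)) stop("window start must precede window end")
  structure(list(start = start, end = end), class = "data_window")
}

#' @export
print.data_window <- function(x, ...) {
  cat(sprintf("<data_window %s .. %s>\n", x$start, x$end))
  invisible(x)
}

#' Completed age in years at a reference date
#'
#' Standard completed-years age: the birthday falling on the reference date
#' counts as completed, the day before does not. Vectorised over both
#' arguments with the usual recycling.
#'
#' @param dob Date of birth (`Date` or ISO-8601 string).
#' @param reference Reference date, must not precede `dob`.
#' @return Integer vector of completed years.
#' @export
#' @examples
#' age_at("2000-06-15", "2050-06-14")  # 49
#' age_at("2000-06-15", "2050-06-15")  # 50
age_at <- function(dob, reference) {
  dob <- as.Date(dob)
  reference <- as.Date(reference)
  if (anyNA(dob) || anyNA(reference)) stop("age_at: dates must be valid")
  n <- max(length(dob), length(reference))
  dob <- rep_len(dob, n)
  reference <- rep_len(reference, n)
  if (any(dob > reference)) stop("age_at: date of birth after reference date")
  dl <- as.POSIXlt(dob)
  rl <- as.POSIXlt(reference)
  age <- rl$year - dl$year
  # subtract one if the birthday has not yet occurred in the reference year
  before <- rl$mon < dl$mon | (rl$mon == dl$mon & rl$mday < dl$mday)
  as.integer(age - before)
}

#' Pseudonymise patient identifiers
#'
#' Replaces sensitive identifiers with opaque `PIDxxxxxx` labels. Inputs are
#' randomly permuted under the given seed and PID numbers assigned in the
#' permuted order, so the label carries no information about the original
#' sort order.
#'
#' @param ids Character vector of unique identifiers.
#' @param seed Integer seed controlling the permutation.
#' @return Named character vector mapping each input id to its PID label.
#' @export
#' @examples
#' pseudonymise(c("S1234567A", "S7654321B"), seed = 1)
pseudonymise <- function(ids, seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("pseudonymise: duplicate input IDs")
  if (length(ids) == 0) return(stats::setNames(character(0), character(0)))
  if (length(ids) > 999999) stop("pseudonymise: more than 999,999 ids cannot fit PID format")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  perm <- sample.int(length(ids))
  out <- character(length(ids))
  out[perm] <- sprintf("PID%06d", seq_along(ids))
  stats::setNames(out, ids)
}

# Save/restore .Random.seed so library calls don't perturb user RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- row-level validation helpers -------------------------------------------

parse_date_col <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")

new_rejects <- function() {
  data.frame(table = character(0), row = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

add_rejects <- function(rej, table, rows, reason) {
  if (length(rows) == 0) return(rej)
  rbind(rej, data.frame(table = table, row = as.integer(rows), reason = reason,
                        stringsAsFactors = FALSE))
}

validate_patients <- function(df) {
  need <- c("patient_id", "sex", "race", "date_of_birth")
  if (!all(need %in% names(df)))
    stop("patients table missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  rej <- new_rejects()
  dob <- parse_date_col(df$date_of_birth)
  bad <- which(is.na(dob))
  rej <- add_rejects(rej, "patients", bad, "malformed date_of_birth")
  bad2 <- which(!(df$sex %in% SEX_LEVELS))
  rej <- add_rejects(rej, "patients", bad2, "unknown sex value")
  bad3 <- which(!(df$race %in% RACE_LEVELS))
  rej <- add_rejects(rej, "patients", bad3, "unknown race value")
  dup <- which(duplicated(df$patient_id))
  rej <- add_rejects(rej, "patients", dup, "duplicate patient_id")
  drop <- unique(c(bad, bad2, bad3, dup))
  keep <- setdiff(seq_len(nrow(df)), drop)
  out <- data.frame(patient_id = as.character(df$patient_id[keep]),
                    sex = as.character(df$sex[keep]),
                    race = as.character(df$race[keep]),
                    date_of_birth = dob[keep],
                    stringsAsFactors = FALSE)
  list(data = out, rejects = rej)
}

validate_problems <- function(df, patient_ids) {
  need <- c("patient_id", "code", "code_system", "description", "entry_date")
  if (!all(need %in% names(df)))
    stop("problems table missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  rej <- new_rejects()
  d <- parse_date_col(df$entry_date)
  bad <- which(is.na(d))
  rej <- add_rejects(rej, "problems", bad, "malformed entry_date")
  bad2 <- which(!(df$code_system %in% CODE_SYSTEMS))
  rej <- add_rejects(rej, "problems", bad2, "unknown code_system")
  bad3 <- which(is.na(df$code) | !nzchar(as.character(df$code)))
  rej <- add_rejects(rej, "problems", bad3, "empty code")
  bad4 <- which(!(df$patient_id %in% patient_ids))
  rej <- add_rejects(rej, "problems", bad4, "patient_id not in patients table")
  keep <- setdiff(seq_len(nrow(df)), unique(c(bad, bad2, bad3, bad4)))
  out <- data.frame(patient_id = as.character(df$patient_id[keep]),
                    code = as.character(df$code[keep]),
                    code_system = as.character(df$code_system[keep]),
                    description = as.character(df$description[keep]),
                    entry_date = d[keep], stringsAsFactors = FALSE)
  list(data = out, rejects = rej)
}

validate_labs <- function(df, patient_ids) {
  need <- c("patient_id", "analyte", "value", "units", "draw_date")
  if (!all(need %in% names(df)))
    stop("labs table missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  rej <- new_rejects()
  d <- parse_date_col(df$draw_date)
  val <- suppressWarnings(as.numeric(df$value))
  units <- as.character(df$units)
  analyte <- as.character(df$analyte)
  bad <- which(is.na(d))
  rej <- add_rejects(rej, "labs", bad, "malformed draw_date")
  bad2 <- which(is.na(val) | val < 0)
  rej <- add_rejects(rej, "labs", bad2, "negative or non-numeric value")
  bad3 <- which(!(analyte %in% ANALYTES))
  rej <- add_rejects(rej, "labs", bad3, "unknown analyte")
  bad4 <- which(!(df$patient_id %in% patient_ids))
  rej <- add_rejects(rej, "labs", bad4, "patient_id not in patients table")
  # LDL-C unit normalisation: mg/dL accepted and converted; anything else
  # for LDL_C is unconvertible and rejected rather than silently coerced.
  is_ldl <- analyte == "LDL_C"
  mgdl <- which(is_ldl & tolower(units) %in% c("mg/dl", "mgdl"))
  if (length(mgdl)) {
    val[mgdl] <- val[mgdl] / MG_DL_PER_MMOL_L
    units[mgdl] <- "mmol/L"
  }
  bad5 <- which(is_ldl & !(tolower(units) %in% "mmol/l"))
  rej <- add_rejects(rej, "labs", bad5, "unconvertible LDL-C units")
  keep <- setdiff(seq_len(nrow(df)), unique(c(bad, bad2, bad3, bad4, bad5)))
  out <- data.frame(patient_id = as.character(df$patient_id[keep]),
                    analyte = analyte[keep], value = val[keep],
                    units = units[keep], draw_date = d[keep],
                    stringsAsFactors = FALSE)
  list(data = out, rejects = rej, n_converted = length(mgdl))
}

validate_meds <- function(df, patient_ids) {
  need <- c("patient_id", "drug_name", "dose_mg", "start_date", "end_date")
  if (!all(need %in% names(df)))
    stop("meds table missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  rej <- new_rejects()
  s <- parse_date_col(df$start_date)
  end_raw <- as.character(df$end_date)
  open <- is.na(end_raw) | !nzchar(end_raw)
  e <- parse_date_col(df$end_date)
  dose <- suppressWarnings(as.numeric(df$dose_mg))
  bad <- which(is.na(s))
  rej <- add_rejects(rej, "meds", bad, "malformed start_date")
  bad2 <- which(!open & is.na(e))
  rej <- add_rejects(rej, "meds", bad2, "malformed end_date")
  bad3 <- which(is.na(dose) | dose <= 0)
  rej <- add_rejects(rej, "meds", bad3, "non-positive dose_mg")
  bad4 <- which(!open & !is.na(e) & !is.na(s) & s > e)
  rej <- add_rejects(rej, "meds", bad4, "start_date after end_date")
  bad5 <- which(!(df$patient_id %in% patient_ids))
  rej <- add_rejects(rej, "meds", bad5, "patient_id not in patients table")
  keep <- setdiff(seq_len(nrow(df)), unique(c(bad, bad2, bad3, bad4, bad5)))
  out <- data.frame(patient_id = as.character(df$patient_id[keep]),
                    drug_name = as.character(df$drug_name[keep]),
                    dose_mg = dose[keep], start_date = s[keep],
                    end_date = e[keep], stringsAsFactors = FALSE)
  list(data = out, rejects = rej)
}

#' Read a four-table EHR cohort from CSV files
#'
#' Loads and validates `patients.csv`, `problems.csv`, `labs.csv` and
#' `meds.csv`. Rows violating an invariant (malformed date, unknown enum
#' value, negative lab value, non-positive dose, inverted medication
#' interval, or a `patient_id` absent from the patients table) are rejected
#' with a row-level diagnostic, never silently coerced. LDL-C results
#' reported in mg/dL are converted to mmol/L (divide by 38.67).
#'
#' @param patients_path,problems_path,labs_path,meds_path CSV file paths.
#' @return An object of class `ehr_cohort`: a list with data frames
#'   `patients`, `problems`, `labs`, `meds` and a `rejects` data frame
#'   (`table`, `row`, `reason`).
#' @seealso [write_cohort()], [read_cohort_dir()]
#' @export
read_cohort <- function(patients_path, problems_path, labs_path, meds_path) {
  for (p in c(patients_path, problems_path, labs_path, meds_path))
    if (!file.exists(p)) stop("missing file: ", p)
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = "character")
  pat <- validate_patients(rd(patients_path))
  ids <- pat$data$patient_id
  prob <- validate_problems(rd(problems_path), ids)
  lab <- validate_labs(rd(labs_path), ids)
  med <- validate_meds(rd(meds_path), ids)
  rejects <- rbind(pat$rejects, prob$rejects, lab$rejects, med$rejects)
  if (nrow(rejects))
    message(sprintf("read_cohort: rejected %d row(s); see $rejects", nrow(rejects)))
  if (isTRUE(lab$n_converted > 0))
    message(sprintf("read_cohort: converted %d LDL-C result(s) from mg/dL to mmol/L",
                    lab$n_converted))
  structure(list(patients = pat$data, problems = prob$data, labs = lab$data,
                 meds = med$data, rejects = rejects),
            class = "ehr_cohort")
}

#' Read a cohort from a directory of standard CSV names
#'
#' Convenience wrapper over [read_cohort()] expecting `patients.csv`,
#' `problems.csv`, `labs.csv`, `meds.csv` under `dir`.
#'
#' @param dir Directory containing the four CSV tables.
#' @return An `ehr_cohort` object.
#' @export
read_cohort_dir <- function(dir) {
  read_cohort(file.path(dir, "patients.csv"), file.path(dir, "problems.csv"),
              file.path(dir, "labs.csv"), file.path(dir, "meds.csv"))
}

#' Write a cohort to CSV files
#'
#' Writes the four tables in the documented schema. Dates are serialised as
#' ISO-8601; an open medication end date becomes an empty field. Output is
#' byte-stable: rows are written in their stored order with fixed headers,
#' so identical cohorts produce identical files.
#'
#' @param cohort An `ehr_cohort` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  p <- cohort$patients
  p$date_of_birth <- fmt_date(p$date_of_birth)
  pr <- cohort$problems
  pr$entry_date <- fmt_date(pr$entry_date)
  lb <- cohort$labs
  lb$draw_date <- fmt_date(lb$draw_date)
  lb$value <- format_num(lb$value)
  md <- cohort$meds
  md$start_date <- fmt_date(md$start_date)
  md$end_date <- fmt_date(md$end_date)
  md$dose_mg <- format_num(md$dose_mg)
  paths <- file.path(dir, c("patients.csv", "problems.csv", "labs.csv", "meds.csv"))
  utils::write.csv(p, paths[1], row.names = FALSE, quote = TRUE)
  utils::write.csv(pr, paths[2], row.names = FALSE, quote = TRUE)
  utils::write.csv(lb, paths[3], row.names = FALSE, quote = TRUE)
  utils::write.csv(md, paths[4], row.names = FALSE, quote = TRUE)
  invisible(paths)
}

# Fixed-precision numeric formatting keeps CSV round-trips lossless at the
# day/assay precision this data carries.
format_num <- function(x) {
  out <- formatC(x, format = "f", digits = 6, drop0trailing = TRUE)
  out[is.na(x)] <- ""
  out
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort: %d patients, %d problems, %d labs, %d meds, %d rejects>\n",
              nrow(x$patients), nrow(x$problems), nrow(x$labs), nrow(x$meds),
              nrow(x$rejects)))
  invisible(x)
}

#' Construct an in-memory cohort from the four tables
#'
#' Lower-level constructor used by the synthetic generator and tests;
#' performs the same row validation as [read_cohort()].
#'
#' @param patients,problems,labs,meds Data frames in the documented schema.
#' @return An `ehr_cohort` object.
#' @export
as_ehr_cohort <- function(patients, problems, labs, meds) {
  pat <- validate_patients(patients)
  ids <- pat$data$patient_id
  prob <- validate_problems(problems, ids)
  lab <- validate_labs(labs, ids)
  med <- validate_meds(meds, ids)
  structure(list(patients = pat$data, problems = prob$data, labs = lab$data,
                 meds = med$data,
                 rejects = rbind(pat$rejects, prob$rejects, lab$rejects, med$rejects)),
            class = "ehr_cohort")
}
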