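# Builders for tiny in-code fixtures used across the suite. All column
# arguments recycle against `ids`, so zero-length ids give empty tables.

patients_df <- function(ids, sex = "male", race = "chinese",
                        dob = "1980-01-01") {
  n <- length(ids)
  data.frame(patient_id = ids, sex = rep_len(sex, n), race = rep_len(race, n),
             date_of_birth = rep_len(dob, n), stringsAsFactors = FALSE)
}

problems_df <- function(ids = character(0), desc = character(0),
                        date = "2020-06-01", code = "X", code_system = "local") {
  n <- length(ids)
  data.frame(patient_id = ids, code = rep_len(code, n),
             code_system = rep_len(code_system, n),
             description = rep_len(desc, n), entry_date = rep_len(date, n),
             stringsAsFactors = FALSE)
}

labs_df <- function(ids = character(0), value = numeric(0),
                    date = "2020-06-01", units = "mmol/L", analyte = "LDL_C") {
  n <- length(ids)
  data.frame(patient_id = ids, analyte = rep_len(analyte, n),
             value = rep_len(value, n), units = rep_len(units, n),
             draw_date = rep_len(date, n), stringsAsFactors = FALSE)
}

meds_df <- function(ids = character(0), drug = character(0), dose = numeric(0),
                    start = "2018-06-01", end = "2021-12-31") {
  n <- length(ids)
  data.frame(patient_id = ids, drug_name = rep_len(drug, n),
             dose_mg = rep_len(dose, n), start_date = rep_len(start, n),
             end_date = rep_len(end, n), stringsAsFactors = FALSE)
}

empty_cohort_tables <- function(ids, ...) {
  list(patients = patients_df(ids, ...),
       problems = problems_df(), labs = labs_df(), meds = meds_df())
}

make_cohort <- function(patients, problems = problems_df(),
                        labs = labs_df(), meds = meds_df()) {
  as_ehr_cohort(patients, problems, labs, meds)
}

# random affected-system sets for combinatorics tests
random_system_sets <- function(n) {
  out <- lapply(seq_len(n), function(i) {
    k <- sample(0:5, 1)
    if (k == 0) character(0) else sample(raredetect:::SYSTEMS, k)
  })
  names(out) <- sprintf("P%04d", seq_len(n))
  out
}
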