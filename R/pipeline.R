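# End-to-end pipeline: generate (or load) a cohort, run both screens, and
# summarise (demographics, interaction/Venn tables, LDL-C t-test). Every
# artifact is listed in a run manifest with row counts and a config hash so
# a run is auditable and reproducible from its outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed recorded in the manifest and driving generation.
#' @param cohort_dir Directory with an existing four-table cohort; `NULL`
#'   (default) generates a synthetic cohort instead.
#' @param n_patients Synthetic cohort size (ignored when `cohort_dir` set).
#' @param window A `data_window`.
#' @param catalog_path Optional JSON value-set catalog overriding the
#'   default.
#' @param fh_rules_path Optional YAML file mirroring [fh_rules()] fields.
#' @param fabry,fh,n_near_miss Synthetic-generator overrides, see
#'   [synthetic_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort_dir = NULL,
                            n_patients = 5000, window = data_window(),
                            catalog_path = NULL, fh_rules_path = NULL,
                            fabry = list(), fh = list(), n_near_miss = 50) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_dir = cohort_dir, n_patients = n_patients,
                 window = window, catalog_path = catalog_path,
                 fh_rules_path = fh_rules_path, fabry = fabry, fh = fh,
                 n_near_miss = n_near_miss),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `out_dir`, `seed`, `cohort_dir`, `n_patients`,
#' `window` (`start`, `end`), `catalog`, `fh_rules`, `fabry`, `fh`,
#' `n_near_miss`. Unknown keys are an error (configuration problems fail
#' loudly, exit code 2 at the CLI).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  allowed <- c("out_dir", "seed", "cohort_dir", "n_patients", "window",
               "catalog", "fh_rules", "fabry", "fh", "n_near_miss")
  extra <- setdiff(names(y), allowed)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  win <- if (is.null(y$window)) data_window()
         else data_window(y$window$start, y$window$end)
  pipeline_config(out_dir = y$out_dir %||% "pipeline_out",
                  seed = y$seed %||% 1L, cohort_dir = y$cohort_dir,
                  n_patients = y$n_patients %||% 5000, window = win,
                  catalog_path = y$catalog, fh_rules_path = y$fh_rules,
                  fabry = y$fabry %||% list(), fh = y$fh %||% list(),
                  n_near_miss = y$n_near_miss %||% 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read FH rule thresholds from YAML
#'
#' Keys mirror [fh_rules()] arguments; `high_intensity_statins` is a list
#' of `{drug_name, min_dose_mg}` maps.
#'
#' @param path YAML file.
#' @return An `fh_rules` object.
#' @export
read_fh_rules <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("ascvd_age_male", "ascvd_age_female", "ldl_on_statin",
               "ldl_child", "ldl_adult", "child_age_max",
               "high_intensity_statins")
  extra <- setdiff(names(y), allowed)
  if (length(extra)) stop("unknown FH rules key(s): ", paste(extra, collapse = ", "))
  args <- y[setdiff(names(y), "high_intensity_statins")]
  if (!is.null(y$high_intensity_statins))
    args$high_intensity_statins <- data.frame(
      drug_name = vapply(y$high_intensity_statins, `[[`, character(1), "drug_name"),
      min_dose_mg = vapply(y$high_intensity_statins, function(x)
        as.numeric(x$min_dose_mg), numeric(1)),
      stringsAsFactors = FALSE)
  do.call(fh_rules, args)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  # Dates serialised explicitly so the hash is stable across sessions
  ser <- rapply(unclass(config), function(x)
    if (inherits(x, "Date")) format(x) else x, how = "replace")
  yaml::write_yaml(ser, f)
  unname(tools::md5sum(f))
}

write_table_artifact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Run the full pipeline
#'
#' Stages: obtain a cohort (generate synthetic, or load from
#' `cohort_dir`), screen for Fabry and FH, then summarise. Writes, under
#' `out_dir`: the four input tables (+ `truth.csv` when generated),
#' `fabry_results.csv`, `fh_results.csv`, `demographics.csv`,
#' `interactions_k1.csv`..`interactions_k3.csv`, `venn_regions.csv`,
#' `ttest.json`, and `run_manifest.json` listing every artifact with its
#' row count, the seed and a config hash.
#'
#' The interaction and Venn tables are computed over the affected-system
#' sets of Fabry suspects; the demographics table summarises Fabry and FH
#' suspects separately; the t-test compares qualifying LDL-C between FH
#' known cases and suspects (skipped, with a note, when either group has
#' fewer than two values — known cases only have a qualifying LDL when
#' their lab evidence was planted or recorded).
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- if (is.null(config$catalog_path)) default_catalog()
             else load_catalog(config$catalog_path)
  rules <- if (is.null(config$fh_rules_path)) fh_rules()
           else read_fh_rules(config$fh_rules_path)
  artifacts <- list()
  note <- function(name, path, n) {
    artifacts[[name]] <<- list(path = basename(path), rows = n)
  }

  if (is.null(config$cohort_dir)) {
    sc <- generate_cohort(synthetic_config(
      n_patients = config$n_patients, seed = config$seed,
      window = config$window, fabry = config$fabry, fh = config$fh,
      n_near_miss = config$n_near_miss), catalog = catalog)
    cohort <- sc$cohort
    write_synthetic_cohort(sc, config$out_dir)
    note("truth", "truth.csv", nrow(sc$truth))
  } else {
    cohort <- read_cohort_dir(config$cohort_dir)
    if (nrow(cohort$rejects) > 0) {
      rp <- file.path(config$out_dir, "rejects.csv")
      write_table_artifact(cohort$rejects, rp)
      note("rejects", rp, nrow(cohort$rejects))
    }
    write_cohort(cohort, config$out_dir)
  }
  note("patients", "patients.csv", nrow(cohort$patients))
  note("problems", "problems.csv", nrow(cohort$problems))
  note("labs", "labs.csv", nrow(cohort$labs))
  note("meds", "meds.csv", nrow(cohort$meds))

  fab <- screen_fabry_cohort(cohort, catalog = catalog, window = config$window)
  fp <- file.path(config$out_dir, "fabry_results.csv")
  write_table_artifact(fab$results, fp)
  note("fabry_results", fp, nrow(fab$results))

  fhs <- screen_fh_cohort(cohort, catalog = catalog, rules = rules,
                          window = config$window)
  hp <- file.path(config$out_dir, "fh_results.csv")
  write_table_artifact(fhs$results, hp)
  note("fh_results", hp, nrow(fhs$results))

  # summaries over the suspect cohorts
  fab_sus <- fab$results$patient_id[fab$results$status == "suspect"]
  fh_sus <- fhs$results$patient_id[fhs$results$status == "suspect"]
  demo <- rbind(
    demographics_long(demographics_summary(cohort$patients, fab_sus,
                                           config$window$end), "fabry_suspect"),
    demographics_long(demographics_summary(cohort$patients, fh_sus,
                                           config$window$end), "fh_suspect"))
  dp <- file.path(config$out_dir, "demographics.csv")
  write_table_artifact(demo, dp)
  note("demographics", dp, nrow(demo))

  sus_systems <- fab$systems[fab_sus]
  for (k in 1:3) {
    ik <- interaction_counts(sus_systems, k)
    p <- file.path(config$out_dir, sprintf("interactions_k%d.csv", k))
    write_table_artifact(ik, p)
    note(sprintf("interactions_k%d", k), p, nrow(ik))
  }
  vr <- venn_regions(sus_systems)
  vp <- file.path(config$out_dir, "venn_regions.csv")
  write_table_artifact(vr, vp)
  note("venn_regions", vp, nrow(vr))

  ldl_known <- known_case_ldl(cohort, fhs, config$window)
  ldl_sus <- fhs$results$qualifying_ldl[fhs$results$status == "suspect"]
  ldl_sus <- ldl_sus[!is.na(ldl_sus)]
  tt <- if (length(ldl_known) >= 2 && length(ldl_sus) >= 2 &&
            stats::var(ldl_known) > 0 && stats::var(ldl_sus) > 0) {
    r <- two_sample_t_test(ldl_known, ldl_sus, "welch")
    list(variant = r$variant, t_statistic = r$t_statistic,
         degrees_of_freedom = r$degrees_of_freedom, p_value = r$p_value,
         mean_known = r$mean_a, mean_suspect = r$mean_b,
         n_known = length(ldl_known), n_suspect = length(ldl_sus))
  } else {
    list(note = "t-test skipped: fewer than two LDL-C values in a group",
         n_known = length(ldl_known), n_suspect = length(ldl_sus))
  }
  tp <- file.path(config$out_dir, "ttest.json")
  jsonlite::write_json(tt, tp, auto_unbox = TRUE, digits = NA)
  note("ttest", tp, 1L)

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_patients = nrow(cohort$patients), artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# max in-window LDL-C per FH known case (their diagnostic evidence is the
# code, so any recorded LDL is summarised)
known_case_ldl <- function(cohort, fhs, window) {
  ids <- fhs$results$patient_id[fhs$results$status == "known_case"]
  labs <- cohort$labs
  labs <- labs[labs$patient_id %in% ids & labs$analyte == "LDL_C" &
               labs$draw_date >= window$start & labs$draw_date <= window$end, ,
               drop = FALSE]
  if (!nrow(labs)) return(numeric(0))
  vapply(split(labs$value, labs$patient_id), max, numeric(1))
}

demographics_long <- function(ds, cohort_label) {
  rows <- list()
  add <- function(category, level, count, proportion)
    rows[[length(rows) + 1]] <<- data.frame(
      cohort = cohort_label, category = category, level = level,
      count = count, value = proportion, stringsAsFactors = FALSE)
  for (lv in names(ds$sex_counts))
    add("sex", lv, as.integer(ds$sex_counts[[lv]]),
        if (lv %in% names(ds$sex_props)) unname(ds$sex_props[[lv]]) else NA_real_)
  for (lv in names(ds$race_counts))
    add("race", lv, as.integer(ds$race_counts[[lv]]),
        if (lv %in% names(ds$race_props)) unname(ds$race_props[[lv]]) else NA_real_)
  for (i in seq_len(nrow(ds$age_by_sex))) {
    r <- ds$age_by_sex[i, ]
    add("age_median", r$sex, r$n, r$median)
    add("age_iqr", r$sex, r$n, r$iqr)
  }
  do.call(rbind, rows)
}
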