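# Value sets: named groups of clinical codes and description synonyms
# treated as one filterable concept. This is the mechanism that copes with
# coding and spelling variants ("hypercholesterolemia" vs
# "hypercholesterolaemia") so a concept filter is defined once and reused.

#' Normalise a clinical description string
#'
#' Lowercases, trims, and collapses internal whitespace runs to a single
#' space. Description matching is exact on this canonical form — no fuzzy
#' matching.
#'
#' @param x Character vector.
#' @return Canonicalised character vector.
#' @export
normalise_description <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Construct a value set
#'
#' @param name Concept label (non-empty).
#' @param codes Data frame with columns `system` (one of `"SNOMED"`,
#'   `"local"`) and `code`, or `NULL`.
#' @param synonyms Character vector of description synonyms; lowercased and
#'   whitespace-normalised, duplicates dropped.
#' @return An object of class `value_set`.
#' @export
#' @examples
#' value_set("FH", codes = data.frame(system = "SNOMED", code = "398036000"),
#'           synonyms = c("familial hypercholesterolemia",
#'                        "familial hypercholesterolaemia"))
value_set <- function(name, codes = NULL, synonyms = character(0)) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("value_set: name must be a non-empty string")
  if (is.null(codes)) {
    codes <- data.frame(system = character(0), code = character(0),
                        stringsAsFactors = FALSE)
  } else {
    codes <- data.frame(system = as.character(codes$system),
                        code = as.character(codes$code),
                        stringsAsFactors = FALSE)
    if (any(!codes$system %in% CODE_SYSTEMS))
      stop("value_set: unknown code system")
    if (any(!nzchar(codes$code))) stop("value_set: empty code")
    codes <- unique(codes)
  }
  synonyms <- sort(unique(normalise_description(synonyms)))
  synonyms <- synonyms[nzchar(synonyms)]
  if (nrow(codes) == 0 && length(synonyms) == 0)
    stop("value_set: definition must contain at least one code or synonym")
  structure(list(name = name, codes = codes, synonyms = synonyms),
            class = "value_set")
}

#' Alias constructor matching the field vocabulary
#' @rdname value_set
#' @export
build_value_set <- value_set

#' @export
print.value_set <- function(x, ...) {
  cat(sprintf("<value_set '%s': %d code(s), %d synonym(s)>\n",
              x$name, nrow(x$codes), length(x$synonyms)))
  invisible(x)
}

#' Does a problem-list entry match a value set?
#'
#' True iff the entry's `(code_system, code)` pair is in the set's codes, or
#' its normalised description equals one of the set's synonyms. A code match
#' takes precedence (short-circuits) over description matching.
#'
#' @param vs A `value_set`.
#' @param entry A list or one-row data frame with `code`, `code_system`,
#'   `description`.
#' @return Logical scalar.
#' @export
matches <- function(vs, entry) {
  stopifnot(inherits(vs, "value_set"))
  key <- paste(entry$code_system, entry$code, sep = "\r")
  if (key %in% paste(vs$codes$system, vs$codes$code, sep = "\r")) return(TRUE)
  normalise_description(entry$description) %in% vs$synonyms
}

#' Construct a value-set catalog
#'
#' @param sets List of `value_set` objects; names must be unique.
#' @param version Catalog version string.
#' @return An object of class `value_set_catalog`.
#' @export
value_set_catalog <- function(sets, version = "1") {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "value_set")))
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("value_set_catalog: duplicate set names")
  structure(list(version = as.character(version),
                 sets = stats::setNames(sets, nms)),
            class = "value_set_catalog")
}

#' @export
print.value_set_catalog <- function(x, ...) {
  cat(sprintf("<value_set_catalog v%s: %d sets>\n", x$version, length(x$sets)))
  invisible(x)
}

#' Save a catalog as JSON
#'
#' Schema: `{"version": str, "sets": [{"name", "codes": [{"system","code"}],
#' "synonyms": [str]}]}`. The round trip through [load_catalog()] is
#' lossless.
#'
#' @param catalog A `value_set_catalog`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "value_set_catalog"))
  sets <- lapply(unname(catalog$sets), function(vs) {
    codes <- lapply(seq_len(nrow(vs$codes)), function(i)
      list(system = vs$codes$system[i], code = vs$codes$code[i]))
    list(name = vs$name, codes = codes, synonyms = as.list(vs$synonyms))
  })
  jsonlite::write_json(list(version = catalog$version, sets = sets), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a catalog from JSON
#'
#' Strict: an unknown field anywhere in the document is an error naming the
#' field and its JSON location.
#'
#' @param path JSON file path.
#' @return A `value_set_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("load_catalog: no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_fields(doc, c("version", "sets"), "/")
  if (is.null(doc$version) || is.null(doc$sets))
    stop("load_catalog: catalog requires 'version' and 'sets' at /")
  sets <- lapply(seq_along(doc$sets), function(i) {
    s <- doc$sets[[i]]
    loc <- sprintf("/sets/%d", i - 1)
    check_fields(s, c("name", "codes", "synonyms"), loc)
    if (is.null(s$name)) stop("load_catalog: missing 'name' at ", loc)
    codes <- NULL
    if (length(s$codes)) {
      for (j in seq_along(s$codes))
        check_fields(s$codes[[j]], c("system", "code"),
                     sprintf("%s/codes/%d", loc, j - 1))
      codes <- data.frame(
        system = vapply(s$codes, function(x) as.character(x$system), character(1)),
        code = vapply(s$codes, function(x) as.character(x$code), character(1)),
        stringsAsFactors = FALSE)
    }
    value_set(s$name, codes = codes,
              synonyms = unlist(s$synonyms, use.names = FALSE))
  })
  value_set_catalog(sets, version = doc$version)
}

check_fields <- function(x, allowed, loc) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("load_catalog: unknown field '%s' at %s", extra[1], loc))
  invisible(TRUE)
}

# ---- cohort-wide matching ----------------------------------------------------

# Matches every problem row against every set in the catalog in one pass.
# Returns a data frame (row, set) with one line per (problem row, matching
# set) pair. Used by both screens; equivalent to looping matches() but
# vectorised via keyed joins.
match_problems <- function(problems, catalog) {
  stopifnot(inherits(catalog, "value_set_catalog"))
  empty <- data.frame(row = integer(0), set = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(problems) == 0) return(empty)
  code_lut <- do.call(rbind, lapply(catalog$sets, function(vs) {
    if (nrow(vs$codes) == 0) return(NULL)
    data.frame(set = vs$name,
               key = paste(vs$codes$system, vs$codes$code, sep = "\r"),
               stringsAsFactors = FALSE)
  }))
  syn_lut <- do.call(rbind, lapply(catalog$sets, function(vs) {
    if (length(vs$synonyms) == 0) return(NULL)
    data.frame(set = vs$name, key = vs$synonyms, stringsAsFactors = FALSE)
  }))
  hits <- list()
  if (!is.null(code_lut)) {
    pk <- data.frame(row = seq_len(nrow(problems)),
                     key = paste(problems$code_system, problems$code, sep = "\r"),
                     stringsAsFactors = FALSE)
    hits$code <- merge(pk, code_lut, by = "key")[, c("row", "set")]
  }
  if (!is.null(syn_lut)) {
    pk <- data.frame(row = seq_len(nrow(problems)),
                     key = normalise_description(problems$description),
                     stringsAsFactors = FALSE)
    hits$syn <- merge(pk, syn_lut, by = "key")[, c("row", "set")]
  }
  out <- unique(do.call(rbind, c(list(empty), unname(hits))))
  rownames(out) <- NULL
  out[order(out$row, out$set), , drop = FALSE]
}

# ---- default catalog ---------------------------------------------------------

#' Default clinical value-set catalog
#'
#' Ships the phenotype concepts used by the Fabry and FH screens. No
#' licensed terminology is distributed: each concept carries a placeholder
#' `local` code plus its description synonyms (including common -ise/-ize
#' and -aemia/-emia spelling variants), so the pipeline is runnable and
#' testable without a SNOMED licence. Real deployments override the catalog
#' via JSON ([load_catalog()]).
#'
#' @return A `value_set_catalog`.
#' @export
default_catalog <- function() {
  vs <- function(name, syns, snomed = NULL) {
    codes <- data.frame(system = "local",
                        code = paste0("LC-", toupper(gsub("[^a-z0-9]+", "-", name))),
                        stringsAsFactors = FALSE)
    if (!is.null(snomed))
      codes <- rbind(codes, data.frame(system = "SNOMED", code = snomed))
    value_set(name, codes = codes, synonyms = syns)
  }
  value_set_catalog(list(
    # kidney
    vs("chronic_kidney_disease", c("chronic kidney disease", "ckd")),
    vs("proteinuria", "proteinuria"),
    vs("microalbuminuria", "microalbuminuria"),
    # cardiac
    vs("cardiomyopathy", c("cardiomyopathy", "hypertrophic cardiomyopathy")),
    vs("valvular_heart_disease", c("valvular heart disease", "heart valve disorder")),
    vs("arrhythmia", c("arrhythmia", "cardiac arrhythmia")),
    # neuro
    vs("stroke_ischemic", c("stroke ischemic", "ischemic stroke", "ischaemic stroke")),
    vs("transient_ischemic_attack",
       c("transient ischemic attack", "transient ischaemic attack", "tia")),
    vs("acroparaesthesia", c("acroparaesthesia", "acroparesthesia")),
    # skin
    vs("angiokeratomas", c("angiokeratomas", "angiokeratoma")),
    vs("hypohidrosis", c("hypohidrosis", "impaired sweating",
                         "impaired sweating/hypohidrosis")),
    vs("heat_cold_intolerance", c("heat and cold tolerance",
                                  "heat and cold intolerance")),
    # eye
    vs("corneal_whirling", "corneal whirling"),
    vs("cornea_verticillata", c("cornea verticillate", "cornea verticillata")),
    vs("corneal_lenticular_opacities",
       c("corneal and lenticular opacities", "corneal opacity", "lenticular opacity")),
    vs("retinal_vasculopathy", c("vasculopathy (retina, conjunctiva)",
                                 "retinal vasculopathy", "conjunctival vasculopathy")),
    # disease diagnoses (known-case detection)
    vs("fabry_disease", c("fabry disease", "anderson-fabry disease")),
    value_set("familial_hypercholesterolaemia",
              codes = data.frame(system = c("local", "SNOMED"),
                                 code = c("LC-FAMILIAL-HYPERCHOLESTEROLAEMIA",
                                          "398036000"),
                                 stringsAsFactors = FALSE),
              synonyms = c("familial hypercholesterolemia",
                           "familial hypercholesterolaemia")),
    # premature-ASCVD qualifying events
    vs("ascvd", c("myocardial infarction", "angina", "unstable angina",
                  "coronary revascularisation", "coronary revascularization",
                  "ischemic stroke", "ischaemic stroke",
                  "peripheral arterial disease"))
  ), version = "1")
}
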