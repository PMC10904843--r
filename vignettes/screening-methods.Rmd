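---
title: "Rule-based EHR screening for Fabry disease and familial hypercholesterolaemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based EHR screening for Fabry disease and familial hypercholesterolaemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredetect)
```

## The problem

Rare genetic diseases are chronically underdiagnosed: patients accumulate
years of organ-specific care before anyone connects the dots. Structured
EHR data — problem lists, laboratory results, medication orders — already
contains those dots. This package implements a deliberately simple,
auditable case-finding strategy: encode published diagnostic red flags as
deterministic rules over the structured tables, flag "suspects" for expert
chart review, and quantify the gap between diagnosed prevalence and
expected population prevalence.

Two diseases with well-defined, structurally-inferable criteria are
covered: Fabry disease (an X-linked lysosomal storage disorder with renal,
cardiac, neurological, cutaneous and ocular manifestations; background
incidence about 1 in 100,000) and familial hypercholesterolaemia (FH;
severely elevated LDL cholesterol causing premature atherosclerotic
cardiovascular disease, ASCVD; population prevalence in Singapore estimated
near 1 in 250).

A screen like this is a triage instrument, not a diagnostic test: output
must be reviewed clinically, and a flagged patient may have a more plausible
secondary cause (e.g. hypertensive nephropathy explaining a kidney + cardiac
+ neuro combination).

## Data model

Four flat CSV tables: `patients` (pseudonymous id, sex, race, date of
birth), `problems` (coded problem-list entries with free-text
descriptions), `labs` (analyte, value, units, draw date) and `meds` (drug,
dose in mg, order interval). Validation is row-level and loud: a malformed
date, unknown enum value, negative lab value or orphan patient id rejects
that row with a diagnostic; nothing is silently coerced. LDL-C arriving in
mg/dL is converted to mmol/L (divide by 38.67) and logged.

Identifier pseudonymisation follows the randomise-then-number pattern:
inputs are randomly permuted under a seed and assigned sequential
`PIDxxxxxx` labels, so the label ordering carries no information.

Dates are day-level ISO-8601. Ages are completed years; the birthday falling
on the reference date counts as completed.

## Value sets

A value set is a named concept carrying a set of `(code_system, code)`
pairs and a set of description synonyms. Matching is exact: a problem entry
matches if its code pair is in the set or its normalised description
(lowercased, whitespace-collapsed) equals a synonym. No fuzzy matching, no
terminology-hierarchy expansion — reproducibility is the point, and both
are explicit non-goals.

The shipped default catalog carries placeholder `local` codes plus the
phenotype names as synonyms (including -emia/-aemia variants), because no
licensed terminology can be distributed. Deployments on real data should
override it via JSON with their actual SNOMED CT value sets; the JSON
loader is strict and names the offending field on schema violations.

## Screening rules

### Fabry

`suspect` iff completed age at the reference date is **strictly** under 50
and at least **two** of the five organ systems (kidney, cardiac, neuro,
skin, eye) contain at least one matching problem entry. Entry multiplicity
is irrelevant — five kidney phenotypes are still one system. A match of the
Fabry diagnosis value set makes the patient a `known_case`, which preempts
suspect status: known and suspect cohorts are disjoint, mirroring how true
positives and suspects are reported separately.

Two genuinely open choices, decided as follows:

* **Age reference.** The rule's age could be judged at each problem entry
  or once per patient. Default is once, at the data-window end — the
  simplest reading of a point-in-time population filter — with
  `age_reference = "per_event"` available (systems then count only entries
  recorded before the 50th birthday).
* **Window visibility.** Whether diagnoses outside the extraction window
  are visible at all is data-dependent; the window filter is therefore
  configurable (`window_filter`), defaulting to on, with the standard
  window 1 Jan 2018 – 1 Mar 2022.

### FH

`suspect` iff **any** clause fires:

| clause | condition | age basis |
|---|---|---|
| premature ASCVD | earliest ASCVD event at age < 55 (male) / < 60 (female) | event date |
| statin | LDL-C > 2.6 mmol/L with an active high-intensity statin covering the draw | draw date |
| child | LDL-C > 3.9 mmol/L and age ≤ 18 | draw date |
| adult | LDL-C > 4.9 mmol/L and age > 18 | draw date |

All thresholds strict as printed; a patient aged exactly 18 at the draw is
evaluated only by the child rule. Prematurity is an onset property, so the
ASCVD age is anchored at the **earliest** matching event date rather than
the window end — a documented interpretation, not a stated method.
"Adhering to high-intensity statins" is operationalised as at least one
order for a drug on the high-intensity list (default atorvastatin ≥ 40 mg,
rosuvastatin ≥ 20 mg, the standard ACC/AHA class definition) at or above
the minimum dose, whose interval covers the draw date; a missing end date
means the order is open. This is a proxy — structured orders carry no
dispensing or proportion-of-days-covered information — and should be read
as such. Patients of unknown sex are not evaluable by the ASCVD clause
(logged), but remain evaluable by the LDL clauses.

`qualifying_ldl` reports the maximum LDL-C among rule-firing results, the
natural "worst value" summary for review.

## Analytics

* **Interaction counts** (orders 1–3 in the pipeline, 1–5 in the API) use
  superset containment: the count for {cardiac, renal} is the number of
  patients whose affected set contains both. **Venn regions** count exact
  set equality over all 31 non-empty subsets. The two are linked by the
  inclusion identity — order-k count = sum of Venn regions over supersets —
  which the tests verify on random cohorts. Both are computed because
  published "interaction" bar charts and Venn diagrams genuinely differ in
  semantics, and single-system tallies cannot be reconciled with a
  ≥ 2-system suspect rule under either reading alone.
* **Demographics**: sex/race counts with proportions over non-missing
  levels, per-sex age median (midpoint convention for even n) and IQR with
  type-7 linear-interpolation quartiles — stated so results are
  reproducible across software.
* **t-test**: authored closed-form, two-sided; Welch is the default since
  known-case and suspect cohorts can differ in size by orders of magnitude,
  with the pooled variant retained for comparison. The suite checks both
  against `stats::t.test` to 1e-10.
* **Prevalence arithmetic**: `prevalence_one_in_n` (ties away from zero,
  optional rounding granularity: 161 cases in 1.28 M is "1 in 8,000" at the
  nearest thousand), `percent_increase`, and `expected_cases` (ceiling =
  conservative lower bound: 1.28 M × 1e-5 → at least 13 expected cases).

## The synthetic generator: what a green test establishes

`generate_cohort()` produces the four tables plus a per-patient truth
manifest. Its defaults are the stated world the screens are validated in:
a 5,000-patient miniature with 4 Fabry known cases, 20 Fabry suspects, 16
FH known cases, 120 FH suspects and 50 near-miss decoys; race mix
0.61/0.155/0.117/0.118 (Chinese/Malay/Indian/other); Fabry suspects 60:40
male:female with ages triangular on [18, 49], mode 41, honouring a median
just above 40; FH suspects 58% female; adult suspect LDL-C a shifted
log-normal strictly above 4.9 mmol/L, right-skewed and concentrated near
the flag level, with a 1% extreme tail in (20, 25) mmol/L. FH suspects are
planted 55/15/15/15% across the adult/child/statin/ASCVD clauses.

Near-miss decoys each violate exactly one clause: age 50+ with
multi-system phenotypes (half sit exactly on the age-50 boundary), under-50
with a single system (sometimes several phenotypes of that one system, to
exercise deduplication), LDL exactly at a threshold (strict `>` must not
fire), and a statin below the high-intensity dose. Half the Fabry known
cases also carry suspect-like evidence, exercising preemption.

Design choices worth knowing:

* **Single labelling.** One archetype per patient. Ischaemic stroke
  legitimately belongs to both the Fabry neuro system and the ASCVD value
  set; the generator therefore plants neuro evidence using descriptions not
  shared with the ASCVD set, so a planted Fabry suspect can never
  incidentally satisfy the FH screen. The screens themselves handle
  overlapping value sets without special casing — this is purely a property
  of the stated test world.
* **Sub-streams.** Each generation stage reseeds from the base seed with a
  fixed offset, so generation is deterministic given the config —
  byte-identical CSVs on rerun, which the suite asserts.
* **Realism limits.** No longitudinal disease trajectories, no real SNOMED
  codes, no missing-data mechanisms, no comorbidity correlation structure,
  all sexes known. A green screen-recovery test therefore establishes that
  the rules are implemented exactly as specified on clean, well-coded data
  — it says nothing about sensitivity to real-world coding noise, which is
  the clinical validation step this package cannot replace.

## Numerical conventions and degenerate inputs

Empty cohorts screen to empty results with zero counts, not errors; an
empty demographic subset yields an empty summary. The t-test refuses groups
with n < 2 or zero variance in both groups. Unconvertible LDL units reject
that result (logged), never the patient. Venn regions of an empty mapping
are 31 zeros. `prevalence_one_in_n` is undefined at zero cases and errors.

## Known limitations

* Statin adherence is order-interval coverage, not dispensing-based.
* Description matching is exact after normalisation; misspelled free text
  in real problem lists will be missed unless added to the value set.
* The default catalog's codes are placeholders; real deployments must
  supply their terminology.
* The pipeline's t-test compares qualifying/recorded LDL-C between known
  cases and suspects on synthetic data; published p-values from protected
  datasets are not reproduced and not asserted anywhere.
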