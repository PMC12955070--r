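---
title: "Assessing the quality of rare-disease EHR data with raredq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the quality of rare-disease EHR data with raredq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredq)
```

## The problem

Rare diseases (RDs) are mostly invisible in routine hospital data: the
ICD-10-GM codes used in German claims data subsume most RDs under
unspecific categories, so a single code may stand for one rare disease,
several, or a mixture of rare and common conditions. Orphacodes — the
numeric identifiers of the Orphanet nomenclature — disambiguate RD
entities, and the Alpha-ID-SE terminology (the alphabetical index of
ICD-10-GM, extended with an Orphacode field per diagnostic term) bridges
the two systems. Because RD cohorts are small, every record matters:
quality defects that would be shrugged off in common-disease research can
sink an RD study. And because research access to hospital data
increasingly runs through standardized FHIR renderings produced by ETL
pipelines, the transformation itself can silently introduce such defects.

`raredq` measures this. It assesses one dataset on a harmonized set of
counting parameters and normalized indicators, and compares a directly
exported reference dataset with its transformed counterpart to quantify
what the transformation lost.

## Tracer diagnoses

The terminology module parses a pipe-delimited Alpha-ID-SE-style file
(configurable field layout, see `alpha_dialect()`) and derives the
*tracer* set: ICD-10-GM codes for which **every** valid diagnostic term
carries an Orphacode. Such codes exclusively code rare diseases, so their
presence marks an RD case even when no Orphacode was documented.

```{r}
term <- parse_alpha_id_se(c(
  "1|I128560|Q87.5|||2097|Grant syndrome",
  "1|I128737|Q87.5|||1824|Lowry-Wood syndrome",
  "1|I200003|E84.0|||586|Cystic fibrosis with pulmonary manifestations",
  "1|I300002|G12.9||||Unannotated motor neuron term"))
derive_tracers(term)$codes   # G12.9 has an unannotated term: not a tracer
```

Only entries flagged valid participate in tracer derivation and link
checking; retired entries are kept for audit. Codes occurring on secondary
(star) positions do not participate in tracer derivation — the tracer
property is defined over the primary code of a term. A curated expert list
can be loaded with `load_curated_tracers()` as an alternative provenance.

## Parameters and indicators

`dq_assess()` computes thirteen counting parameters. P1–P3 count treatment
cases (RD cases, Orphacoded cases, tracer cases — distinct case ids, on
raw records as loaded); P4–P6 normalize them per 100,000 inpatient cases
(half-up rounding to integers); P7–P13 count issues: missing mandatory
items, missing mandatory values, outliers, missing Orphacodes on tracer
diagnoses, implausible ICD/Orphacode links, duplicate case records
(surplus records per identical case/patient/ICD/Orphacode group, i.e. the
number of removable records), and ambiguous RD cases.

Seven indicators map these onto 0–100%:

| indicator | dimension | formula |
|---|---|---|
| `dqi_co_ocr` | completeness | `100(1 − P10 / tracer diagnoses)` |
| `dqi_co_icr` | completeness | `100(1 − P7 / mandatory items)` |
| `dqi_co_vcr` | completeness | `100(1 − P8 / value slots)` |
| `dqi_pl_opr` | plausibility | `100(1 − P11 / linked diagnoses)` |
| `dqi_pl_rpr` | plausibility | `100(1 − P9 / checked values)` |
| `dqi_un_cur` | uniqueness | `100(1 − P13 / P1)` |
| `dqi_un_cdr` | uniqueness | `100(1 − P12 / case records)` |

The indicators are defined verbally in the literature; the denominators
here are the unique choice under which the published rate bounds for
unambiguity (above 94%) and Orphacoding plausibility (above 97%) are
reproduced from the published counts, which the test suite checks. A zero
denominator makes an indicator non-evaluable: it reports 0 with a
`vacuous` flag rather than `NA`, so that a dataset without any Orphacodes
shows 0% on the Orphacode-related indicators instead of dropping them.

Mandatory items are plain configuration (`default_item_catalog()`, 15
items across the Person / Treatment Case / Diagnosis modules). The exact
item list of a given profile release varies, so the default is an explicit
approximation and any study should pin its own catalog. Item-level absence
(no record carries any value) is counted once in P7 and its value slots
are excluded from the P8 denominator; value-level absence is counted per
slot in P8.

Range plausibility is rule-driven (`default_outlier_rules()`): age at
admission at most 130 years, discharge not before admission, and no
special characters in code fields — malformed codes are a value-level
plausibility defect, not a load failure, which is why they are handled
here rather than at parse time. Absent values are never outliers; the
denominator counts only values actually checked. Dates are ISO-8601;
legally reduced precision (year or year–month) counts as a present value
for completeness but is excluded from date arithmetic.

## Ambiguity

An RD case is ambiguous when its coding cannot be resolved to a single
rare disease. Rule (a): a diagnosis lacks an Orphacode while its ICD code
is a tracer with more than one candidate Orphacode. Rule (b) is this
package's interpretation of an "ambiguous link" and is switchable
(`ambiguity_rule_b = FALSE`): the diagnosis carries both codes, the ICD
code is a multi-candidate tracer, and the pair is not in the terminology —
the recorded Orphacode then fails to single out one of the candidate
disorders. A plausible pair on a multi-candidate code is *not* ambiguous:
the Orphacode did its job. Each ambiguous case counts once in P13
regardless of how many ambiguous diagnoses it carries.

## Comparing two datasets

`lost_parameters()` applies the piecewise loss rule: for the issue-count
parameters i = 7, 8, 9 the loss is `Pi_transformed − Pi_reference` (more
is worse there); for every other parameter it is
`Pi_reference − Pi_transformed`. Negative losses are reported, never
clamped, because manual curation in claims-data creation can insert data.
Positive losses of P9 (outliers) and P12 (duplicates) are classified
`possibly-intentional` rather than `issue` — curation may legitimately
remove such records. We note that under the sign convention a positive P9
loss means *more* outliers in the transformed dataset; the conservative
classification is kept nevertheless, because the direction of curation
cannot be established from counts alone.

`summarize_lost()` books the positive completeness losses (P1, P7, P8,
P10) into a completeness-loss total, then adds the transformed dataset's
ambiguous cases and the mandatory items missing in *both* datasets
(`min(P7_ref, P7_transformed)`) to obtain the grand issue total of the
transformed dataset. Relative parameters are compared only when both
inpatient totals are known and equal; comparability of the two parameter
sets (same catalog, tracer set and terminology) is enforced via a
fingerprint.

## Reporting and k-anonymity

`write_reports()` writes a *DQ Metrics Report* sheet (parameters,
denominators, indicators) and a *DQ Violations Report* sheet (one row per
issue group, grouped by category and group key such as the ICD code), as a
SpreadsheetML workbook plus deterministic CSV fallbacks. Because violation
rows can identify patients in small cohorts, any group covering fewer than
`k` distinct patients (default 5) is folded into an aggregate
`suppressed (<k)` row; item-level rows carry no patient locus and are
exempt. `k = 1` disables suppression.

## The synthetic-fixture generator

Real PAS exports cannot be shared, so `gen_dataset_pair()` builds paired
CSV and FHIR-NDJSON renderings of the same synthetic cohort from one
ledger, with exact planted issues per category and optional degradation
switches that emulate a FAIRification pipeline (`drop_all_orphacodes`
reproduces the claims-data scenario in which Orphacodes never reach the
transformed dataset; `drop_case_fraction` removes cases outright). The
ledger records the expected full parameter set of both datasets — computed
by an independent plain-loop recount and cross-checked against the planted
arithmetic at generation time — and the expected loss vector, so the
engine can be validated end to end.

Defaults were chosen once as a realistic ward-scale extract: 40 patients,
60 inpatient cases within the 2021 study year, admissions uniform over the
year with stays of 1–14 days, a terminology of 8 single-Orphacode tracers,
2 multi-Orphacode tracers and 4 non-tracer codes, and single-digit planted
counts per issue category. Identifiers are deterministic in the seed, so
fixtures diff cleanly. Planted issues are mutually exclusive per record to
keep the ledger exact, with one definitional coupling: an ambiguous case
planted as a multi-candidate tracer without an Orphacode is necessarily
also a missing-Orphacode issue, so the expected P10 is
`missing_orphacodes + ambiguous_cases`.

What the generator does *not* emulate: realistic disease prevalence,
coding-habit correlations, free-text artifacts, multi-diagnosis case
structures beyond duplicates, or re-identification risk. Passing tests on
these fixtures therefore demonstrate correctness of the counting and
comparison machinery, not robustness to every real-world PAS export.

```{r}
pair <- gen_dataset_pair(fixture_spec(
  seed = 7, degradation = list(drop_all_orphacodes = TRUE)))
a <- dq_assess(pair$reference, pair$terminology, tracers = pair$tracers)
b <- dq_assess(pair$degraded, pair$terminology, tracers = pair$tracers)
dq_compare(a, b)$summary
```

## Numerical and degenerate-input choices

* Relative frequencies round half-up to integers.
* A code with zero valid terminology entries is not a tracer; an empty
  terminology yields an empty tracer set and every link implausible.
* Duplicate grouping treats "Orphacode absent" as its own key value, so an
  uncoded and a coded record never collapse into one group.
* More than 50% malformed terminology lines reject the file (naming the
  first offending line); below that, malformed lines are collected as
  parse errors, never silently dropped.
* Paged FHIR retrieval merges order-independently (dedup by resource id,
  sorted), so any worker count reproduces the sequential dataset; pages
  are retried a bounded number of times.

## Problem sizes

The test suite and the acceptance script run entirely on generated
fixtures of 15–60 cases (100 random specifications in the recovery
property test) plus the published case counts for the arithmetic checks;
the full suite completes in well under a minute on a single CPU.

## Limitations

The tracer mechanism inherits the incompleteness of any terminology
release: codes whose terms are not yet consistently Orphacode-annotated
cannot become tracers, so tracer-based case counts are lower bounds. The
ambiguity rule (b) is an interpretation and can be switched off. The
comparison attributes losses to the transformation as a whole — it cannot
localize them to a specific ETL stage. P1 counts raw (non-deduplicated)
cases; P12 reports what deduplication would remove.
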