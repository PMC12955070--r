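# DQ engine: issue detectors, the 13 counting parameters and the 7
# normalized indicators.

ISSUE_CATEGORIES <- c("missing_item", "missing_value", "outlier",
                      "missing_orphacode", "implausible_link",
                      "duplicate_case", "ambiguous_case")

issue_frame <- function(category = character(0), record_type = character(0),
                        record_id = character(0), patient_id = character(0),
                        detail = character(0), group_key = character(0)) {
  stopifnot(all(category %in% ISSUE_CATEGORIES))
  data.frame(category = category, record_type = record_type,
             record_id = record_id, patient_id = patient_id,
             detail = detail, group_key = group_key,
             stringsAsFactors = FALSE)
}

#' Construct a DQ parameter set
#'
#' Holds the 13 counting parameters: the observation-unit counts P1-P3
#' (RD / Orpha / tracer cases), their per-100,000 normalizations P4-P6,
#' and the issue counts P7-P13 (missing items, missing values, outliers,
#' missing Orphacodes, implausible links, duplicates, ambiguous cases),
#' together with the denominators the indicators need. Enforces
#' `max(P2,P3) <= P1 <= P2+P3`.
#'
#' @param rdCase,orphaCase,tracerCase P1-P3 (non-negative counts).
#' @param im_misg,vm_misg,vo,oc_misg,link_ip,rdCase_dup,rdCase_amb P7-P13.
#' @param n_items,n_value_slots,n_checked_values,n_tracer_diagnoses,n_linked_diagnoses,n_case_records
#'   indicator denominators.
#' @param total_inpatient_cases optional; enables P4-P6.
#' @param fingerprint comparability fingerprint (catalog + tracer set),
#'   checked by [lost_parameters()].
#' @return object of class `"dq_parameter_set"`; P4-P6 are `NA` when the
#'   total is unknown.
#' @export
dq_parameter_set <- function(rdCase = 0, orphaCase = 0, tracerCase = 0,
                             im_misg = 0, vm_misg = 0, vo = 0, oc_misg = 0,
                             link_ip = 0, rdCase_dup = 0, rdCase_amb = 0,
                             n_items = 0, n_value_slots = 0,
                             n_checked_values = 0, n_tracer_diagnoses = 0,
                             n_linked_diagnoses = 0, n_case_records = 0,
                             total_inpatient_cases = NULL,
                             fingerprint = NULL) {
  counts <- c(rdCase = rdCase, orphaCase = orphaCase, tracerCase = tracerCase,
              im_misg = im_misg, vm_misg = vm_misg, vo = vo, oc_misg = oc_misg,
              link_ip = link_ip, rdCase_dup = rdCase_dup,
              rdCase_amb = rdCase_amb)
  if (any(counts < 0)) stop("DQ parameters must be non-negative", call. = FALSE)
  if (rdCase < max(orphaCase, tracerCase) || rdCase > orphaCase + tracerCase)
    stop("invariant violated: max(P2,P3) <= P1 <= P2+P3", call. = FALSE)
  rel <- relative_frequencies(c(rdCase, orphaCase, tracerCase),
                              total_inpatient_cases, warn = FALSE)
  structure(list(
    rdCase = rdCase, orphaCase = orphaCase, tracerCase = tracerCase,
    rdCase_rel = rel[[1]], orphaCase_rel = rel[[2]], tracerCase_rel = rel[[3]],
    im_misg = im_misg, vm_misg = vm_misg, vo = vo, oc_misg = oc_misg,
    link_ip = link_ip, rdCase_dup = rdCase_dup, rdCase_amb = rdCase_amb,
    n_items = n_items, n_value_slots = n_value_slots,
    n_checked_values = n_checked_values,
    n_tracer_diagnoses = n_tracer_diagnoses,
    n_linked_diagnoses = n_linked_diagnoses, n_case_records = n_case_records,
    total_inpatient_cases = total_inpatient_cases,
    fingerprint = fingerprint
  ), class = "dq_parameter_set")
}

# Canonical order and 1-based index of the 13 parameters.
DQ_PARAM_NAMES <- c("rdCase", "orphaCase", "tracerCase", "rdCase_rel",
                    "orphaCase_rel", "tracerCase_rel", "im_misg", "vm_misg",
                    "vo", "oc_misg", "link_ip", "rdCase_dup", "rdCase_amb")

#' @export
print.dq_parameter_set <- function(x, ...) {
  cat("DQ parameters (P1-P13):\n")
  for (i in seq_along(DQ_PARAM_NAMES)) {
    v <- x[[DQ_PARAM_NAMES[i]]]
    cat(sprintf("  P%-2d %-15s %s\n", i, DQ_PARAM_NAMES[i],
                if (is.null(v) || is.na(v)) "NA" else format(v)))
  }
  invisible(x)
}

#' Normalize case counts to 100,000 inpatient cases
#'
#' `Pi_rel = 100000 * Pi / total`, rounded half-up to integer (so 0.5 goes
#' to 1). With an unknown total the relative parameters are absent (`NA`)
#' and a warning is emitted.
#'
#' @param counts numeric vector of case counts (P1-P3).
#' @param total_inpatient_cases positive integer or `NULL`.
#' @param warn emit the missing-total warning.
#' @return numeric vector of the same length.
#' @export
relative_frequencies <- function(counts, total_inpatient_cases, warn = TRUE) {
  if (is.null(total_inpatient_cases) || is.na(total_inpatient_cases)) {
    if (warn)
      warning("total_inpatient_cases unknown: relative frequencies not computed",
              call. = FALSE)
    return(rep(NA_real_, length(counts)))
  }
  stopifnot(total_inpatient_cases > 0)
  floor(1e5 * counts / total_inpatient_cases + 0.5)
}

#' Classify cases as RD / Orpha / tracer cases
#'
#' A treatment case is an Orpha case iff at least one of its diagnoses
#' carries an Orphacode, a tracer case iff at least one diagnosis ICD code
#' is in the tracer set, and an RD case iff either holds. P1-P3 count
#' distinct case ids.
#'
#' @param ds a `case_dataset`.
#' @param tracers a `tracer_set` (Alpha-ID-SE-derived for the intended P3
#'   semantics).
#' @return list with `flags` (data.frame: case_id, orpha_case, tracer_case,
#'   rd_case) and counts `rdCase`, `orphaCase`, `tracerCase`.
#' @export
classify_cases <- function(ds, tracers) {
  stopifnot(inherits(ds, "case_dataset"), inherits(tracers, "tracer_set"))
  d <- ds$diagnoses[!is.na(ds$diagnoses$case_id), , drop = FALSE]
  ids <- unique(d$case_id)
  has_orpha <- tapply(!is.na(d$orphacode), d$case_id, any)
  has_tracer <- tapply(!is.na(d$icd_code) & d$icd_code %in% tracers$codes,
                       d$case_id, any)
  flags <- data.frame(case_id = ids,
                      orpha_case = unname(has_orpha[ids]),
                      tracer_case = unname(has_tracer[ids]),
                      stringsAsFactors = FALSE)
  flags$rd_case <- flags$orpha_case | flags$tracer_case
  list(flags = flags,
       rdCase = sum(flags$rd_case), orphaCase = sum(flags$orpha_case),
       tracerCase = sum(flags$tracer_case))
}

records_of <- function(ds, type) {
  switch(type, patient = ds$patients, encounter = ds$encounters,
         diagnosis = ds$diagnoses)
}

record_key <- function(type) {
  switch(type, patient = "patient_id", encounter = "case_id",
         diagnosis = "condition_id")
}

# Which catalog items are present at item level (some record of the type
# carries a value)?
item_presence <- function(ds, catalog) {
  vapply(seq_len(nrow(catalog)), function(i) {
    rec <- records_of(ds, catalog$record_type[i])
    f <- catalog$field[i]
    f %in% names(rec) && any(has_value(rec[[f]]))
  }, logical(1))
}

#' Detect missing mandatory data items (P7)
#'
#' A mandatory item is missing iff no record of its type in the dataset
#' carries any value for it (a dataset without any record of the type has
#' all of that type's items missing). Item-level absence is metadata-level:
#' the item's value slots are excluded from the value-completeness
#' denominator.
#'
#' @param ds a `case_dataset`.
#' @param catalog mandatory-item catalog, see [default_item_catalog()].
#' @return list(issues, count, n_items).
#' @export
detect_missing_items <- function(ds, catalog = ds$item_catalog) {
  validate_item_catalog(catalog)
  present <- item_presence(ds, catalog)
  miss <- which(!present)
  list(issues = issue_frame(
         category = rep("missing_item", length(miss)),
         record_type = catalog$record_type[miss],
         record_id = rep(NA_character_, length(miss)),
         patient_id = rep(NA_character_, length(miss)),
         detail = sprintf("mandatory item '%s' (%s) carries no value in any record",
                          catalog$item[miss], catalog$module[miss]),
         group_key = catalog$item[miss]),
       count = length(miss), n_items = nrow(catalog))
}

#' Detect missing mandatory data values (P8)
#'
#' For every record and every mandatory item of its type that is present at
#' item level, an absent value counts once. The denominator is the number
#' of value slots inspected (records x present items of their type).
#'
#' @inheritParams detect_missing_items
#' @return list(issues, count, n_value_slots).
#' @export
detect_missing_values <- function(ds, catalog = ds$item_catalog) {
  validate_item_catalog(catalog)
  present <- item_presence(ds, catalog)
  issues <- list(); n_slots <- 0L
  for (i in which(present)) {
    rec <- records_of(ds, catalog$record_type[i])
    f <- catalog$field[i]
    n_slots <- n_slots + nrow(rec)
    miss <- which(!has_value(rec[[f]]))
    if (length(miss) > 0) {
      key <- record_key(catalog$record_type[i])
      issues[[length(issues) + 1L]] <- issue_frame(
        category = rep("missing_value", length(miss)),
        record_type = rep(catalog$record_type[i], length(miss)),
        record_id = as.character(rec[[key]][miss]),
        patient_id = if ("patient_id" %in% names(rec))
          as.character(rec$patient_id[miss]) else rep(NA_character_, length(miss)),
        detail = sprintf("missing value for mandatory item '%s'", catalog$item[i]),
        group_key = rep(catalog$item[i], length(miss)))
    }
  }
  issues <- if (length(issues) > 0) do.call(rbind, issues) else issue_frame()
  list(issues = issues, count = nrow(issues), n_value_slots = n_slots)
}

#' Outlier rule set
#'
#' Range/format plausibility rules over data values. Each rule is a list
#' with `id`, `record_type`, `fields` (columns it reads; validated against
#' the data model), `description`, and `fun(ds) -> list(bad, n_checked)`
#' where `bad` is a data.frame with columns record_id, patient_id, detail.
#' Absent values are never outliers; they simply are not checked.
#'
#' The defaults implement: age at admission no greater than `max_age`
#' years; discharge date not before admission date; and no characters
#' outside `A-Z`, `0-9` and `.` in code fields (special characters in
#' diagnosis codes are a recurring plausibility defect in claims data).
#'
#' @param max_age upper plausible age at admission, in years.
#' @return list of rules.
#' @export
default_outlier_rules <- function(max_age = 130) {
  list(
    list(id = "age_at_admission", record_type = "encounter",
         fields = c("admission_date", "birth_date"),
         description = sprintf("age at admission must not exceed %d years", max_age),
         fun = function(ds) {
           e <- ds$encounters
           b <- ds$patients$birth_date[match(e$patient_id, ds$patients$patient_id)]
           adm <- parse_day_date(e$admission_date); bd <- parse_day_date(b)
           chk <- !is.na(adm) & !is.na(bd)
           age <- as.numeric(adm - bd) / 365.25
           bad <- which(chk & age > max_age)
           list(bad = data.frame(record_id = e$case_id[bad],
                                 patient_id = e$patient_id[bad],
                                 detail = sprintf("age at admission %.0f years", age[bad]),
                                 stringsAsFactors = FALSE),
                n_checked = sum(chk))
         }),
    list(id = "discharge_after_admission", record_type = "encounter",
         fields = c("admission_date", "discharge_date"),
         description = "discharge date must not precede admission date",
         fun = function(ds) {
           e <- ds$encounters
           adm <- parse_day_date(e$admission_date)
           dis <- parse_day_date(e$discharge_date)
           chk <- !is.na(adm) & !is.na(dis)
           bad <- which(chk & dis < adm)
           list(bad = data.frame(record_id = e$case_id[bad],
                                 patient_id = e$patient_id[bad],
                                 detail = sprintf("discharge %s precedes admission %s",
                                                  e$discharge_date[bad],
                                                  e$admission_date[bad]),
                                 stringsAsFactors = FALSE),
                n_checked = sum(chk))
         }),
    list(id = "code_characters", record_type = "diagnosis",
         fields = "icd_code",
         description = "diagnosis codes must not contain special characters",
         fun = function(ds) {
           d <- ds$diagnoses
           chk <- !is.na(d$icd_code)
           bad <- which(chk & grepl("[^A-Z0-9.]", d$icd_code))
           list(bad = data.frame(record_id = d$condition_id[bad],
                                 patient_id = d$patient_id[bad],
                                 detail = sprintf("code '%s' contains special characters",
                                                  d$icd_code[bad]),
                                 stringsAsFactors = FALSE),
                n_checked = sum(chk))
         })
  )
}

#' Detect outlier data values (P9)
#'
#' Applies an [default_outlier_rules()]-style rule set. The denominator is
#' the number of values actually checked (absent values are not checked).
#' A rule naming a field unknown to the data model is a configuration
#' error.
#'
#' @param ds a `case_dataset`.
#' @param rules a rule set.
#' @return list(issues, count, n_checked_values).
#' @export
detect_outliers <- function(ds, rules = default_outlier_rules()) {
  issues <- list(); n_checked <- 0L
  model_cols <- list(patient = PATIENT_COLS, encounter = ENCOUNTER_COLS,
                     diagnosis = DIAGNOSIS_COLS)
  for (r in rules) {
    known <- c(model_cols[[r$record_type]], "birth_date")
    unknown <- setdiff(r$fields, unique(unlist(model_cols)))
    if (is.null(model_cols[[r$record_type]]) || length(unknown) > 0)
      stop(sprintf("outlier rule '%s' references unknown field(s): %s",
                   r$id, paste(unknown, collapse = ", ")), call. = FALSE)
    res <- r$fun(ds)
    n_checked <- n_checked + res$n_checked
    if (nrow(res$bad) > 0)
      issues[[length(issues) + 1L]] <- issue_frame(
        category = rep("outlier", nrow(res$bad)),
        record_type = rep(r$record_type, nrow(res$bad)),
        record_id = res$bad$record_id, patient_id = res$bad$patient_id,
        detail = res$bad$detail, group_key = rep(r$id, nrow(res$bad)))
  }
  issues <- if (length(issues) > 0) do.call(rbind, issues) else issue_frame()
  list(issues = issues, count = nrow(issues), n_checked_values = n_checked)
}

#' Detect missing Orphacodes on tracer diagnoses (P10)
#'
#' Every diagnosis whose ICD code is a tracer but which lacks an Orphacode
#' is an Orphacoding-completeness issue. Denominator: number of tracer
#' diagnoses.
#'
#' @param ds a `case_dataset`.
#' @param tracers an Alpha-ID-SE-derived `tracer_set`.
#' @return list(issues, count, n_tracer_diagnoses).
#' @export
detect_missing_orphacodes <- function(ds, tracers) {
  d <- ds$diagnoses
  is_tracer <- !is.na(d$icd_code) & d$icd_code %in% tracers$codes
  bad <- which(is_tracer & is.na(d$orphacode))
  list(issues = issue_frame(
         category = rep("missing_orphacode", length(bad)),
         record_type = rep("diagnosis", length(bad)),
         record_id = d$condition_id[bad], patient_id = d$patient_id[bad],
         detail = sprintf("tracer diagnosis %s lacks an Orphacode", d$icd_code[bad]),
         group_key = d$icd_code[bad]),
       count = length(bad), n_tracer_diagnoses = sum(is_tracer))
}

#' Detect implausible ICD-10-GM/Orphacode links (P11)
#'
#' Every diagnosis carrying both codes whose pair is not present in the
#' terminology is an implausible link. Denominator: number of linked
#' diagnoses (both codes present).
#'
#' @param ds a `case_dataset`.
#' @param term an `alpha_terminology`.
#' @return list(issues, count, n_linked_diagnoses).
#' @export
detect_implausible_links <- function(ds, term) {
  d <- ds$diagnoses
  linked <- which(!is.na(d$icd_code) & !is.na(d$orphacode))
  verdict <- check_link(term, d$icd_code[linked], d$orphacode[linked])
  bad <- linked[verdict == "implausible"]
  list(issues = issue_frame(
         category = rep("implausible_link", length(bad)),
         record_type = rep("diagnosis", length(bad)),
         record_id = d$condition_id[bad], patient_id = d$patient_id[bad],
         detail = sprintf("combination %s / %d not found in terminology",
                          d$icd_code[bad], d$orphacode[bad]),
         group_key = d$icd_code[bad]),
       count = length(bad), n_linked_diagnoses = length(linked))
}

#' Detect duplicated RD case records (P12)
#'
#' Diagnosis-bearing case records are grouped by the 4-tuple (case id,
#' patient id, ICD-10-GM code, Orphacode-or-absent); each group of size g
#' contributes its g-1 surplus records. P12 is thus the number of removable
#' records. Denominator: total number of diagnosis records.
#'
#' @param ds a `case_dataset`.
#' @return list(issues, count, n_case_records).
#' @export
detect_duplicates <- function(ds) {
  d <- ds$diagnoses
  key <- paste(d$case_id, d$patient_id, d$icd_code,
               ifelse(is.na(d$orphacode), "-", d$orphacode), sep = "\r")
  surplus <- which(duplicated(key))
  list(issues = issue_frame(
         category = rep("duplicate_case", length(surplus)),
         record_type = rep("diagnosis", length(surplus)),
         record_id = d$condition_id[surplus], patient_id = d$patient_id[surplus],
         detail = sprintf("duplicate of case %s / %s / %s", d$case_id[surplus],
                          d$patient_id[surplus], d$icd_code[surplus]),
         group_key = ifelse(is.na(d$icd_code[surplus]), "(no ICD)",
                            d$icd_code[surplus])),
       count = length(surplus), n_case_records = nrow(d))
}

#' Detect ambiguous RD cases (P13)
#'
#' An RD case is ambiguous iff at least one of its diagnoses cannot be
#' resolved to a single rare disease: (a) the diagnosis lacks an Orphacode
#' while its ICD code is a tracer with more than one candidate Orphacode;
#' or (b, interpretation, switchable) the diagnosis carries both codes, the
#' ICD code is a multi-candidate tracer, and the recorded pair is not in
#' the terminology, so the Orphacode cannot disambiguate the code. Each
#' ambiguous case counts once.
#'
#' @param ds a `case_dataset`.
#' @param term an `alpha_terminology`.
#' @param tracers an Alpha-ID-SE-derived `tracer_set`.
#' @param rule_b apply interpretation rule (b).
#' @return list(issues, count).
#' @export
detect_ambiguous <- function(ds, term, tracers, rule_b = TRUE) {
  d <- ds$diagnoses
  cls <- classify_cases(ds, tracers)
  rd_cases <- cls$flags$case_id[cls$flags$rd_case]

  codes <- unique(d$icd_code[!is.na(d$icd_code) & d$icd_code %in% tracers$codes])
  ncand <- vapply(codes, function(c) length(orpha_candidates(term, c)), integer(1))
  multi <- codes[ncand > 1]

  amb_a <- is.na(d$orphacode) & !is.na(d$icd_code) & d$icd_code %in% multi
  amb_b <- rep(FALSE, nrow(d))
  if (rule_b) {
    linked <- !is.na(d$orphacode) & !is.na(d$icd_code) & d$icd_code %in% multi
    if (any(linked))
      amb_b[linked] <- check_link(term, d$icd_code[linked],
                                  d$orphacode[linked]) == "implausible"
  }
  amb <- (amb_a | amb_b) & !is.na(d$case_id) & d$case_id %in% rd_cases
  amb_cases <- unique(d$case_id[amb])
  trigger_icd <- d$icd_code[amb][match(amb_cases, d$case_id[amb])]
  pat <- d$patient_id[amb][match(amb_cases, d$case_id[amb])]
  list(issues = issue_frame(
         category = rep("ambiguous_case", length(amb_cases)),
         record_type = rep("encounter", length(amb_cases)),
         record_id = amb_cases, patient_id = pat,
         detail = sprintf("case carries ambiguous RD diagnosis %s", trigger_icd),
         group_key = trigger_icd),
       count = length(amb_cases))
}

#' Compute the 7 normalized DQ indicators
#'
#' Each indicator maps an issue count and its denominator onto the 0-100
#' scale (100 = no issues). A zero denominator makes the indicator
#' non-evaluable: it reports 0 with the `vacuous` flag set, so that e.g.
#' Orphacode-related indicators of a dataset without any Orphacodes read 0.
#'
#' \describe{
#'   \item{dqi_co_ocr}{Orphacoding completeness: `100(1 - P10/tracer diagnoses)`}
#'   \item{dqi_co_icr}{item completeness: `100(1 - P7/mandatory items)`}
#'   \item{dqi_co_vcr}{value completeness: `100(1 - P8/value slots)`}
#'   \item{dqi_pl_opr}{Orphacoding plausibility: `100(1 - P11/linked diagnoses)`}
#'   \item{dqi_pl_rpr}{range plausibility: `100(1 - P9/checked values)`}
#'   \item{dqi_un_cur}{RD case unambiguity: `100(1 - P13/P1)`}
#'   \item{dqi_un_cdr}{RD case dissimilarity: `100(1 - P12/case records)`}
#' }
#'
#' @param params a `dq_parameter_set`.
#' @return object of class `"dq_indicator_set"`: data.frame with columns
#'   `indicator`, `dimension`, `value` (in `[0,100]`) and `vacuous`.
#' @export
compute_indicators <- function(params) {
  stopifnot(inherits(params, "dq_parameter_set"))
  rate <- function(issues, denom) {
    if (issues < 0 || denom < 0)
      stop("indicator inputs must be non-negative", call. = FALSE)
    if (denom == 0) return(c(0, TRUE))
    c(max(0, min(100, 100 * (1 - issues / denom))), FALSE)
  }
  m <- rbind(
    dqi_co_ocr = rate(params$oc_misg, params$n_tracer_diagnoses),
    dqi_co_icr = rate(params$im_misg, params$n_items),
    dqi_co_vcr = rate(params$vm_misg, params$n_value_slots),
    dqi_pl_opr = rate(params$link_ip, params$n_linked_diagnoses),
    dqi_pl_rpr = rate(params$vo, params$n_checked_values),
    dqi_un_cur = rate(params$rdCase_amb, params$rdCase),
    dqi_un_cdr = rate(params$rdCase_dup, params$n_case_records)
  )
  out <- data.frame(indicator = rownames(m),
                    dimension = c("completeness", "completeness",
                                  "completeness", "plausibility",
                                  "plausibility", "uniqueness", "uniqueness"),
                    value = m[, 1], vacuous = as.logical(m[, 2]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dq_indicator_set", "data.frame")
  out
}

#' @export
print.dq_indicator_set <- function(x, ...) {
  cat("DQ indicators (0-100, 100 = no issues):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s [%s] %6.2f%s\n", x$indicator[i], x$dimension[i],
                x$value[i], if (x$vacuous[i]) " (vacuous denominator)" else ""))
  invisible(x)
}

param_fingerprint <- function(catalog, tracers, term = NULL) {
  paste(c(paste(catalog$item, collapse = ","),
          paste(tracers$codes, collapse = ","),
          if (!is.null(term)) paste(sort(term$link_set), collapse = ",") else ""),
        collapse = ";")
}

#' Run a full single-dataset DQ assessment
#'
#' Classifies cases, runs all seven issue detectors, assembles the
#' parameter set P1-P13 with its denominators and computes the seven
#' indicators. The issue list length always equals `P7 + ... + P13`.
#'
#' @param ds a `case_dataset`.
#' @param term an `alpha_terminology`.
#' @param tracers tracer set; derived from `term` when `NULL`.
#' @param rules outlier rule set.
#' @param catalog mandatory-item catalog; defaults to the dataset's.
#' @param ambiguity_rule_b see [detect_ambiguous()].
#' @return object of class `"dq_assessment"`: list(params, indicators,
#'   issues, case_flags, dataset_label).
#' @examples
#' term <- parse_alpha_id_se(c("1|I000001|E84.0||E84.0|586|Cystic fibrosis"))
#' ds <- case_dataset(
#'   patients = data.frame(patient_id = "P1", birth_date = "1980-01-01",
#'                         sex = "female", address_city = "X",
#'                         address_postal_code = "1"),
#'   encounters = data.frame(case_id = "C1", patient_id = "P1",
#'                           admission_date = "2021-03-01",
#'                           discharge_date = "2021-03-05",
#'                           encounter_class = "IMP"),
#'   diagnoses = data.frame(condition_id = "D1", case_id = "C1",
#'                          patient_id = "P1", icd_code = "E84.0",
#'                          orphacode = 586L, diagnosis_date = "2021-03-01",
#'                          role = "primary"))
#' dq_assess(ds, term)
#' @export
dq_assess <- function(ds, term, tracers = NULL,
                      rules = default_outlier_rules(),
                      catalog = ds$item_catalog, ambiguity_rule_b = TRUE) {
  stopifnot(inherits(ds, "case_dataset"), inherits(term, "alpha_terminology"))
  if (is.null(tracers)) tracers <- derive_tracers(term)

  cls <- classify_cases(ds, tracers)
  mi <- detect_missing_items(ds, catalog)
  mv <- detect_missing_values(ds, catalog)
  ol <- detect_outliers(ds, rules)
  mo <- detect_missing_orphacodes(ds, tracers)
  il <- detect_implausible_links(ds, term)
  du <- detect_duplicates(ds)
  am <- detect_ambiguous(ds, term, tracers, rule_b = ambiguity_rule_b)

  params <- dq_parameter_set(
    rdCase = cls$rdCase, orphaCase = cls$orphaCase, tracerCase = cls$tracerCase,
    im_misg = mi$count, vm_misg = mv$count, vo = ol$count, oc_misg = mo$count,
    link_ip = il$count, rdCase_dup = du$count, rdCase_amb = am$count,
    n_items = mi$n_items, n_value_slots = mv$n_value_slots,
    n_checked_values = ol$n_checked_values,
    n_tracer_diagnoses = mo$n_tracer_diagnoses,
    n_linked_diagnoses = il$n_linked_diagnoses,
    n_case_records = du$n_case_records,
    total_inpatient_cases = ds$total_inpatient_cases,
    fingerprint = param_fingerprint(catalog, tracers, term))

  issues <- rbind(mi$issues, mv$issues, ol$issues, mo$issues, il$issues,
                  du$issues, am$issues)
  rownames(issues) <- NULL
  structure(list(params = params, indicators = compute_indicators(params),
                 issues = issues, case_flags = cls$flags,
                 dataset_label = ds$provenance),
            class = "dq_assessment")
}

#' @export
print.dq_assessment <- function(x, ...) {
  cat(sprintf("DQ assessment of dataset '%s'\n",
              if (nzchar(x$dataset_label)) x$dataset_label else "unlabelled"))
  cat(sprintf("  %d RD cases (%d Orpha, %d tracer), %d issues detected\n",
              x$params$rdCase, x$params$orphaCase, x$params$tracerCase,
              nrow(x$issues)))
  print(x$indicators)
  invisible(x)
}

#' @export
summary.dq_assessment <- function(object, ...) {
  cat(sprintf("DQ assessment of dataset '%s'\n\n", object$dataset_label))
  print(object$params)
  cat("\n")
  print(object$indicators)
  if (nrow(object$issues) > 0) {
    cat("\nIssues by category:\n")
    print(table(factor(object$issues$category, levels = ISSUE_CATEGORIES)))
  } else cat("\nNo issues detected.\n")
  invisible(object)
}
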