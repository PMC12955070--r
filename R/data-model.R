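# Harmonized case dataset: patients, encounters, diagnoses + item catalog.

PATIENT_COLS <- c("patient_id", "birth_date", "sex", "address_city",
                  "address_postal_code")
ENCOUNTER_COLS <- c("case_id", "patient_id", "admission_date",
                    "discharge_date", "encounter_class")
DIAGNOSIS_COLS <- c("condition_id", "case_id", "patient_id", "icd_code",
                    "orphacode", "diagnosis_date", "role")

#' Default mandatory-item catalog
#'
#' The 15 mandatory data items assessed by the completeness indicators,
#' grouped into the three core modules (Person, Treatment Case, Diagnosis).
#' The exact item list of a given profile release is site- and
#' version-dependent, so the catalog is plain data: pass your own
#' data.frame with the same columns to assess a different profile.
#'
#' @return data.frame with columns `module`, `item`, `record_type`
#'   (`patient`/`encounter`/`diagnosis`) and `field` (the column the item
#'   reads in the harmonized dataset).
#' @export
default_item_catalog <- function() {
  df <- rbind(
    data.frame(module = "Person", record_type = "patient",
               item = c("patient_id", "birth_date", "sex", "address_city",
                        "address_postal_code"),
               field = c("patient_id", "birth_date", "sex", "address_city",
                         "address_postal_code")),
    data.frame(module = "Treatment Case", record_type = "encounter",
               item = c("case_id", "patient_ref", "admission_date",
                        "discharge_date", "encounter_class"),
               field = c("case_id", "patient_id", "admission_date",
                         "discharge_date", "encounter_class")),
    data.frame(module = "Diagnosis", record_type = "diagnosis",
               item = c("condition_id", "case_ref", "icd_code",
                        "diagnosis_date", "diagnosis_role"),
               field = c("condition_id", "case_id", "icd_code",
                         "diagnosis_date", "role"))
  )
  df[, c("module", "item", "record_type", "field")]
}

validate_item_catalog <- function(catalog) {
  need <- c("module", "item", "record_type", "field")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog)))
    stop("item catalog must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(catalog$item))
    stop("item catalog: item names must be unique", call. = FALSE)
  bad <- !catalog$record_type %in% c("patient", "encounter", "diagnosis")
  if (any(bad))
    stop("item catalog: unknown record_type ",
         paste(unique(catalog$record_type[bad]), collapse = ", "), call. = FALSE)
  invisible(catalog)
}

empty_frame <- function(cols) {
  out <- lapply(cols, function(c) if (c == "orphacode") integer(0) else character(0))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

coerce_frame <- function(df, cols, what) {
  if (is.null(df)) return(empty_frame(cols))
  for (c in setdiff(cols, names(df)))
    df[[c]] <- if (c == "orphacode") NA_integer_ else NA_character_
  df <- df[, cols, drop = FALSE]
  for (c in cols)
    df[[c]] <- if (c == "orphacode") as.integer(df[[c]]) else as.character(df[[c]])
  for (c in setdiff(cols, "orphacode"))
    df[[c]][!is.na(df[[c]]) & df[[c]] == ""] <- NA_character_
  rownames(df) <- NULL
  df
}

#' Construct a harmonized case dataset
#'
#' The common container both readers produce: three record collections
#' (patients, encounters, diagnoses) with fixed character/integer columns,
#' the mandatory-item catalog in force, a provenance label, and optionally
#' the total inpatient-case count used to normalize case frequencies to
#' 100,000 inpatient cases.
#'
#' Diagnoses whose `case_id` is absent from the encounters are kept but
#' flagged (attribute `n_orphan_diagnoses`); reference resolution is a
#' quality property, not a load gate.
#'
#' @param patients,encounters,diagnoses data.frames (missing columns are
#'   added as `NA`). Dates are ISO-8601 strings; reduced precision
#'   (`"2021"`, `"2021-03"`) is retained and counts as a present value.
#' @param item_catalog see [default_item_catalog()].
#' @param provenance free label, e.g. `"EXP"` or `"FHIR"`.
#' @param total_inpatient_cases optional positive integer.
#' @return object of class `"case_dataset"`.
#' @export
case_dataset <- function(patients = NULL, encounters = NULL, diagnoses = NULL,
                         item_catalog = default_item_catalog(),
                         provenance = "", total_inpatient_cases = NULL) {
  validate_item_catalog(item_catalog)
  patients <- coerce_frame(patients, PATIENT_COLS, "patients")
  encounters <- coerce_frame(encounters, ENCOUNTER_COLS, "encounters")
  diagnoses <- coerce_frame(diagnoses, DIAGNOSIS_COLS, "diagnoses")
  if (!is.null(total_inpatient_cases)) {
    total_inpatient_cases <- as.integer(total_inpatient_cases)
    stopifnot(length(total_inpatient_cases) == 1, total_inpatient_cases > 0)
  }
  bad <- !is.na(diagnoses$icd_code) & !icd_is_valid(diagnoses$icd_code)
  orphan <- !is.na(diagnoses$case_id) & !diagnoses$case_id %in% encounters$case_id
  structure(list(patients = patients, encounters = encounters,
                 diagnoses = diagnoses, item_catalog = item_catalog,
                 provenance = provenance,
                 total_inpatient_cases = total_inpatient_cases),
            n_orphan_diagnoses = sum(orphan),
            n_nonconformant_icd = sum(bad),
            class = "case_dataset")
}

#' @export
print.case_dataset <- function(x, ...) {
  cat(sprintf("Case dataset [%s]: %d patients, %d encounters, %d diagnoses\n",
              if (nzchar(x$provenance)) x$provenance else "unlabelled",
              nrow(x$patients), nrow(x$encounters), nrow(x$diagnoses)))
  if (!is.null(x$total_inpatient_cases))
    cat(sprintf("  total inpatient cases for normalization: %d\n",
                x$total_inpatient_cases))
  invisible(x)
}

# TRUE where the slot holds a value (reduced-precision dates included).
has_value <- function(x) !is.na(x) & (!is.character(x) | nzchar(x))

# Strict day-precision ISO date -> Date, else NA (reduced precision is a
# present value for completeness but cannot enter date arithmetic).
parse_day_date <- function(x) {
  d <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}", x)
  d[ok] <- as.Date(substr(x[ok], 1, 10), format = "%Y-%m-%d")
  d
}
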