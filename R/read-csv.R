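# PAS-style CSV export reader.

#' Default PAS CSV schema
#'
#' Maps the harmonized field names to CSV column headers. The first ten
#' fields form the mandatory core of a PAS diagnosis export (one row per
#' diagnosis); the remaining four are optional columns recognized when
#' present so that a CSV export can carry the same item coverage as the
#' FHIR rendering. Override any entry to absorb a site-specific layout.
#'
#' @return named character vector `field -> header`.
#' @export
default_csv_schema <- function() {
  c(patient_id = "patient_id", case_id = "case_id",
    admission_date = "admission_date", discharge_date = "discharge_date",
    birth_date = "birth_date", sex = "sex", icd_code = "icd_code",
    orphacode = "orphacode", diagnosis_date = "diagnosis_date",
    diagnosis_role = "diagnosis_role",
    # optional extras
    address_city = "address_city", address_postal_code = "address_postal_code",
    encounter_class = "encounter_class", condition_id = "condition_id")
}

#' Read a PAS-style CSV export
#'
#' Reads a pseudonymized patient-administration-system export (one row per
#' diagnosis) into a [case_dataset()]. Patients and encounters are
#' deduplicated by identifier; conflicting repeated patient or encounter
#' attributes keep the first-seen value, emit a warning and are counted in
#' the `n_attribute_conflicts` attribute. Empty cells become absent values.
#' Orphacodes are normalized (an `"ORPHA:"` prefix is stripped; a
#' non-numeric remainder becomes an absent value counted in
#' `n_invalid_orphacodes`).
#'
#' @param x file path or character vector of CSV lines.
#' @param schema named map `field -> column header`, see
#'   [default_csv_schema()].
#' @param item_catalog,provenance,total_inpatient_cases passed to
#'   [case_dataset()].
#' @return a `case_dataset`.
#' @export
read_pas_csv <- function(x, schema = default_csv_schema(),
                         item_catalog = default_item_catalog(),
                         provenance = "EXP", total_inpatient_cases = NULL) {
  raw <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    utils::read.csv(x, colClasses = "character", check.names = FALSE)
  } else {
    utils::read.csv(text = paste(x, collapse = "\n"),
                    colClasses = "character", check.names = FALSE)
  }

  mandated <- c("patient_id", "case_id")
  missing_cols <- setdiff(schema[mandated], names(raw))
  if (length(missing_cols) > 0)
    stop("CSV schema error: missing mandated column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  col <- function(field) {
    h <- schema[[field]]
    if (is.null(h) || !h %in% names(raw)) rep(NA_character_, nrow(raw))
    else { v <- trimws(raw[[h]]); v[v == ""] <- NA_character_; v }
  }

  orpha <- orpha_normalize(col("orphacode"))
  diagnoses <- data.frame(
    condition_id = col("condition_id"),
    case_id = col("case_id"),
    patient_id = col("patient_id"),
    icd_code = icd_normalize(col("icd_code")),
    orphacode = as.integer(orpha),
    diagnosis_date = col("diagnosis_date"),
    role = col("diagnosis_role"),
    stringsAsFactors = FALSE
  )

  pat_raw <- data.frame(patient_id = col("patient_id"),
                        birth_date = col("birth_date"), sex = col("sex"),
                        address_city = col("address_city"),
                        address_postal_code = col("address_postal_code"),
                        stringsAsFactors = FALSE)
  enc_raw <- data.frame(case_id = col("case_id"), patient_id = col("patient_id"),
                        admission_date = col("admission_date"),
                        discharge_date = col("discharge_date"),
                        encounter_class = col("encounter_class"),
                        stringsAsFactors = FALSE)

  pat <- dedupe_first_seen(pat_raw, "patient_id")
  enc <- dedupe_first_seen(enc_raw, "case_id")
  n_conflicts <- attr(pat, "n_conflicts") + attr(enc, "n_conflicts")
  if (n_conflicts > 0)
    warning(sprintf("%d conflicting repeated attribute value(s); first-seen kept",
                    n_conflicts), call. = FALSE)

  ds <- case_dataset(pat, enc, diagnoses, item_catalog = item_catalog,
                     provenance = provenance,
                     total_inpatient_cases = total_inpatient_cases)
  attr(ds, "n_invalid_orphacodes") <- attr(orpha, "n_invalid")
  attr(ds, "n_attribute_conflicts") <- n_conflicts
  ds
}

# Deduplicate by key, first-seen wins; count rows whose non-NA attributes
# conflict with the kept row.
dedupe_first_seen <- function(df, key) {
  df <- df[!is.na(df[[key]]), , drop = FALSE]
  first <- !duplicated(df[[key]])
  kept <- df[first, , drop = FALSE]
  n_conflicts <- 0L
  if (any(!first)) {
    idx <- match(df[[key]], kept[[key]])
    for (i in which(!first)) {
      a <- unlist(df[i, setdiff(names(df), key)])
      b <- unlist(kept[idx[i], setdiff(names(df), key)])
      if (any(!is.na(a) & !is.na(b) & a != b)) n_conflicts <- n_conflicts + 1L
    }
  }
  rownames(kept) <- NULL
  structure(kept, n_conflicts = n_conflicts)
}

#' Write a case dataset as a PAS-style CSV
#'
#' One row per diagnosis, joined with its encounter and patient attributes
#' under the given schema. Inverse of [read_pas_csv()] for datasets whose
#' encounters all descend from diagnosis rows.
#'
#' @param ds a `case_dataset`.
#' @param path output file.
#' @param schema see [default_csv_schema()].
#' @return `path`, invisibly.
#' @export
write_pas_csv <- function(ds, path, schema = default_csv_schema()) {
  stopifnot(inherits(ds, "case_dataset"))
  d <- ds$diagnoses
  e <- ds$encounters[match(d$case_id, ds$encounters$case_id), , drop = FALSE]
  p <- ds$patients[match(d$patient_id, ds$patients$patient_id), , drop = FALSE]
  out <- data.frame(
    patient_id = d$patient_id, case_id = d$case_id,
    admission_date = e$admission_date, discharge_date = e$discharge_date,
    birth_date = p$birth_date, sex = p$sex,
    icd_code = d$icd_code,
    orphacode = ifelse(is.na(d$orphacode), NA, as.character(d$orphacode)),
    diagnosis_date = d$diagnosis_date, diagnosis_role = d$role,
    address_city = p$address_city, address_postal_code = p$address_postal_code,
    encounter_class = e$encounter_class, condition_id = d$condition_id,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(schema[names(out)])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
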