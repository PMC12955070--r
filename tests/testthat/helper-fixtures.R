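# Shared test fixtures, built in code.

# A small terminology mirroring the well-known coding constellations:
# Q87.5 and F84.2 are multi-Orphacode tracers, E84.0 a single-Orphacode
# tracer, G71.2 a tracer never paired with Orphacode 777, G12.9 a
# non-tracer (one term lacks an Orphacode), plus one retired entry.
paper_like_terminology <- function() {
  parse_alpha_id_se(c(
    "1|I128560|Q87.5|||2097|Grant syndrome",
    "1|I128737|Q87.5|||1824|Lowry-Wood syndrome",
    "1|I200001|F84.2|||778|Rett syndrome",
    "1|I200002|F84.2|||3095|Atypical Rett syndrome",
    "1|I200003|E84.0|||586|Cystic fibrosis with pulmonary manifestations",
    "1|I200004|G71.2|||97245|Myotonic dystrophy type 2",
    "1|I300001|G12.9|||70|Spinal muscular atrophy term",
    "1|I300002|G12.9||||Unannotated motor neuron term",
    "0|I400001|Z99.9|||999|Retired term"
  ))
}

# Minimal single-case dataset builder; override any field per record.
make_ds <- function(diag, enc = NULL, pat = NULL, ...) {
  if (is.null(enc))
    enc <- data.frame(case_id = unique(diag$case_id),
                      patient_id = diag$patient_id[match(unique(diag$case_id),
                                                         diag$case_id)],
                      admission_date = "2021-03-01",
                      discharge_date = "2021-03-05",
                      encounter_class = "IMP", stringsAsFactors = FALSE)
  if (is.null(pat))
    pat <- data.frame(patient_id = unique(diag$patient_id),
                      birth_date = "1980-06-15", sex = "female",
                      address_city = "Nordstadt",
                      address_postal_code = "12345", stringsAsFactors = FALSE)
  case_dataset(pat, enc, diag, ...)
}

diag_row <- function(condition_id = "D1", case_id = "C1", patient_id = "P1",
                     icd_code = "E84.0", orphacode = NA_integer_,
                     diagnosis_date = "2021-03-01", role = "primary") {
  data.frame(condition_id = condition_id, case_id = case_id,
             patient_id = patient_id, icd_code = icd_code,
             orphacode = as.integer(orphacode),
             diagnosis_date = diagnosis_date, role = role,
             stringsAsFactors = FALSE)
}

# Random-but-satisfiable fixture spec for property tests.
random_fixture_spec <- function(seed) {
  set.seed(seed)
  n_pat <- sample(5:20, 1)
  n_cases <- sample(15:40, 1)
  amb <- sample(0:3, 1); mo <- sample(0:3, 1)
  il <- sample(0:3, 1); ol <- sample(0:3, 1)
  clean <- n_cases - (amb + mo + il + ol)
  dup <- sample(0:min(3, clean), 1)
  mv <- sample(0:max(0, min(5, clean - dup - 1)), 1)
  mi <- sample(0:3, 1)
  fixture_spec(
    n_patients = n_pat, n_cases = n_cases,
    planted = list(missing_values = mv, missing_items = mi, outliers = ol,
                   missing_orphacodes = mo, implausible_links = il,
                   duplicates = dup, ambiguous_cases = amb),
    degradation = list(drop_all_orphacodes = sample(c(TRUE, FALSE), 1),
                       drop_case_fraction = sample(c(0, 0.2), 1)),
    seed = seed)
}

# In-process mock of a paged FHIR endpoint: `pages` Condition pages of
# `per_page` resources, one Patient and one Encounter, offset paging.
# `fail_offsets` lists offsets whose first request errors (transient).
make_mock_fhir_fetcher <- function(pages = 3L, per_page = 2L,
                                   fail_offsets = integer(0),
                                   wrong_total_offset = NULL) {
  total <- pages * per_page
  failed_once <- new.env(parent = emptyenv())
  sys <- fhir_systems()
  function(url) {
    type <- sub("^.*/(Patient|Encounter|Condition)\\?.*$", "\\1", url)
    off <- if (grepl("_getpagesoffset=", url))
      as.integer(sub("^.*_getpagesoffset=([0-9]+).*$", "\\1", url)) else 0L
    if (off %in% fail_offsets && is.null(failed_once[[as.character(off)]])) {
      failed_once[[as.character(off)]] <- TRUE
      stop("transient failure")
    }
    if (type == "Patient") {
      entries <- list(list(resource = list(resourceType = "Patient", id = "P1",
                                           birthDate = "1980-01-01",
                                           gender = "female")))
      bundle <- list(resourceType = "Bundle", total = 1L, entry = entries)
    } else if (type == "Encounter") {
      entries <- list(list(resource = list(
        resourceType = "Encounter", id = "C1",
        subject = list(reference = "Patient/P1"),
        period = list(start = "2021-01-01", end = "2021-01-05"),
        class = list(code = "IMP"))))
      bundle <- list(resourceType = "Bundle", total = 1L, entry = entries)
    } else {
      ids <- off + seq_len(per_page)
      ids <- ids[ids <= total]
      entries <- lapply(ids, function(i) list(resource = list(
        resourceType = "Condition", id = sprintf("D%03d", i),
        subject = list(reference = "Patient/P1"),
        encounter = list(reference = "Encounter/C1"),
        code = list(coding = list(list(system = sys$icd, code = "E84.0"))),
        onsetDateTime = "2021-01-02")))
      tot <- if (!is.null(wrong_total_offset) && off == wrong_total_offset)
        total + 1L else total
      bundle <- list(resourceType = "Bundle", total = tot, entry = entries)
    }
    as.character(jsonlite::toJSON(bundle, auto_unbox = TRUE))
  }
}
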