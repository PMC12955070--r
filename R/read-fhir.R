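# MII-CDS-style FHIR readers: NDJSON streams and a paged REST endpoint.

#' Coding-system URLs
#'
#' Condition codings are split by system URL into the ICD-10-GM code and
#' the Orphacode. Defaults follow the German national code systems; both
#' are overridable because profiles name the code systems, not the URLs.
#'
#' @param icd,orpha system URLs.
#' @return named list.
#' @export
fhir_systems <- function(icd = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
                         orpha = "http://www.orpha.net") {
  list(icd = icd, orpha = orpha)
}

#' Read MII-CDS-style FHIR resources from NDJSON
#'
#' Each line of each stream is one FHIR R4 resource of type Patient,
#' Encounter or Condition; Bundle resources are unwrapped into their
#' entries. Unknown resource types are counted and skipped; unparseable
#' lines are collected as parse errors with their line numbers. If no
#' usable resource is found at all, the input is rejected as a format
#' error.
#'
#' @param paths character vector of NDJSON file paths (or a list of
#'   character vectors of lines).
#' @param systems see [fhir_systems()].
#' @param item_catalog,provenance,total_inpatient_cases passed to
#'   [case_dataset()].
#' @return a `case_dataset` with attributes `parse_errors` (data.frame:
#'   file, line, reason) and `n_skipped_resources`.
#' @export
read_fhir_ndjson <- function(paths, systems = fhir_systems(),
                             item_catalog = default_item_catalog(),
                             provenance = "FHIR",
                             total_inpatient_cases = NULL) {
  if (is.character(paths)) paths <- as.list(paths)
  resources <- list()
  err_file <- character(0); err_line <- integer(0); err_reason <- character(0)
  for (s in seq_along(paths)) {
    src <- paths[[s]]
    lines <- if (length(src) == 1 && !grepl("\n", src) && file.exists(src))
      readLines(src, warn = FALSE)
    else unlist(strsplit(src, "\n", fixed = TRUE))
    label <- if (length(src) == 1 && file.exists(src)) src else sprintf("stream %d", s)
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[[i]]))) next
      res <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                      error = function(e) e)
      if (inherits(res, "error") || is.null(res$resourceType)) {
        err_file <- c(err_file, label); err_line <- c(err_line, i)
        err_reason <- c(err_reason, if (inherits(res, "error"))
          conditionMessage(res) else "missing resourceType")
        next
      }
      resources <- c(resources, unwrap_bundle(res))
    }
  }
  parse_errors <- data.frame(file = err_file, line = err_line,
                             reason = err_reason, stringsAsFactors = FALSE)
  out <- resources_to_dataset(resources, systems, item_catalog, provenance,
                              total_inpatient_cases)
  if (nrow(out$patients) + nrow(out$encounters) + nrow(out$diagnoses) == 0)
    stop("FHIR format error: no usable Patient/Encounter/Condition resource found",
         call. = FALSE)
  attr(out, "parse_errors") <- parse_errors
  out
}

unwrap_bundle <- function(res) {
  if (identical(res$resourceType, "Bundle")) {
    out <- lapply(res$entry, function(e) e$resource)
    out[!vapply(out, is.null, logical(1))]
  } else list(res)
}

ref_id <- function(ref) {
  if (is.null(ref) || is.null(ref$reference)) return(NA_character_)
  sub("^.*/", "", ref$reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)

# Convert a list of parsed FHIR resources to a case_dataset. Shared by the
# NDJSON reader and the paged REST client so both retrieval paths are
# guaranteed to harmonize identically.
resources_to_dataset <- function(resources, systems = fhir_systems(),
                                 item_catalog = default_item_catalog(),
                                 provenance = "FHIR",
                                 total_inpatient_cases = NULL) {
  pat <- list(); enc <- list(); dia <- list(); skipped <- 0L
  for (res in resources) {
    rt <- res$resourceType %||% ""
    if (rt == "Patient") {
      addr <- if (length(res$address) > 0) res$address[[1]] else NULL
      pat[[length(pat) + 1L]] <- data.frame(
        patient_id = chr1(res$id), birth_date = chr1(res$birthDate),
        sex = chr1(res$gender),
        address_city = chr1(addr$city),
        address_postal_code = chr1(addr$postalCode),
        stringsAsFactors = FALSE)
    } else if (rt == "Encounter") {
      enc[[length(enc) + 1L]] <- data.frame(
        case_id = chr1(res$id), patient_id = ref_id(res$subject),
        admission_date = date_part(res$period$start),
        discharge_date = date_part(res$period$end),
        encounter_class = chr1(res$class$code),
        stringsAsFactors = FALSE)
    } else if (rt == "Condition") {
      codes <- split_codings(res$code, systems)
      role <- NA_character_
      if (length(res$category) > 0) {
        cc <- res$category[[1]]$coding
        if (length(cc) > 0) role <- chr1(cc[[1]]$code)
      }
      dia[[length(dia) + 1L]] <- data.frame(
        condition_id = chr1(res$id), case_id = ref_id(res$encounter),
        patient_id = ref_id(res$subject),
        icd_code = codes$icd, orphacode = codes$orpha,
        diagnosis_date = date_part(res$onsetDateTime %||% res$recordedDate),
        role = role, stringsAsFactors = FALSE)
    } else {
      skipped <- skipped + 1L
    }
  }
  rb <- function(l) if (length(l) > 0) do.call(rbind, l) else NULL
  patients <- dedupe_first_seen(rb(pat) %||% empty_frame(PATIENT_COLS), "patient_id")
  encounters <- dedupe_first_seen(rb(enc) %||% empty_frame(ENCOUNTER_COLS), "case_id")
  ds <- case_dataset(patients, encounters, rb(dia),
                     item_catalog = item_catalog, provenance = provenance,
                     total_inpatient_cases = total_inpatient_cases)
  attr(ds, "n_skipped_resources") <- skipped
  ds
}

date_part <- function(x) {
  if (is.null(x)) return(NA_character_)
  sub("T.*$", "", as.character(x))
}

split_codings <- function(code, systems) {
  icd <- NA_character_; orpha <- NA_integer_
  for (cd in code$coding %||% list()) {
    sys <- chr1(cd$system)
    if (is.na(sys)) next
    if (sys == systems$icd && is.na(icd)) icd <- icd_normalize(chr1(cd$code))
    if (sys == systems$orpha && is.na(orpha))
      orpha <- orpha_normalize(chr1(cd$code))[[1]]
  }
  list(icd = icd, orpha = orpha)
}

#' Fetch a case dataset from a paged FHIR REST endpoint
#'
#' Retrieves Patient, Encounter and Condition searches page by page. The
#' first page of each search yields the total; the remaining pages are
#' addressed by offset and may be fetched concurrently (`workers > 1`,
#' forked via [parallel::mclapply()]). The merged dataset is
#' order-independent: resources are deduplicated by id and sorted before
#' harmonization, so `workers = n` reproduces `workers = 1` exactly.
#' Transient page failures are retried up to `max_retries` times, then the
#' failing page is named in a hard error. An inconsistent total across
#' pages raises a warning.
#'
#' @param base_url FHIR base URL (e.g. `"https://server/fhir"`).
#' @param types resource types to retrieve.
#' @param query optional named list of extra search parameters per request.
#' @param page_size `_count` per page.
#' @param workers parallel fetch width; 1 is strictly sequential.
#' @param fetcher `function(url) -> character` returning the response body;
#'   the default reads the URL over HTTP(S). Injectable for testing and for
#'   bearer-token transports.
#' @param max_retries bounded retries per page.
#' @param systems,item_catalog,provenance,total_inpatient_cases as in
#'   [read_fhir_ndjson()].
#' @return a `case_dataset`.
#' @export
fetch_fhir <- function(base_url, types = c("Patient", "Encounter", "Condition"),
                       query = NULL, page_size = 100L, workers = 1L,
                       fetcher = NULL, max_retries = 3L,
                       systems = fhir_systems(),
                       item_catalog = default_item_catalog(),
                       provenance = "FHIR", total_inpatient_cases = NULL) {
  stopifnot(page_size >= 1, workers >= 1)
  if (is.null(fetcher)) fetcher <- http_fetcher
  qs <- ""
  if (length(query) > 0)
    qs <- paste0("&", paste(names(query), unlist(query), sep = "=", collapse = "&"))

  fetch_page <- function(url) {
    for (attempt in seq_len(max_retries + 1L)) {
      body <- tryCatch(fetcher(url), error = function(e) e)
      if (!inherits(body, "error"))
        return(jsonlite::fromJSON(paste(body, collapse = "\n"),
                                  simplifyVector = FALSE))
    }
    stop(sprintf("FHIR page failed after %d retries: %s", max_retries, url),
         call. = FALSE)
  }

  resources <- list()
  for (type in types) {
    url1 <- sprintf("%s/%s?_count=%d%s", sub("/$", "", base_url), type,
                    page_size, qs)
    b1 <- fetch_page(url1)
    total <- b1$total %||% NA_integer_
    pages <- list(b1)
    if (!is.na(total) && total > page_size) {
      offsets <- seq(page_size, total - 1L, by = page_size)
      urls <- paste0(url1, "&_getpagesoffset=", offsets)
      pages <- c(pages, if (workers > 1L)
        parallel::mclapply(urls, fetch_page, mc.cores = workers)
        else lapply(urls, fetch_page))
    } else if (is.na(total)) {
      # no total: follow "next" links sequentially
      b <- b1
      repeat {
        nxt <- NULL
        for (lk in b$link %||% list())
          if (identical(lk$relation, "next")) nxt <- lk$url
        if (is.null(nxt)) break
        b <- fetch_page(nxt)
        pages <- c(pages, list(b))
      }
    }
    for (b in pages) {
      if (inherits(b, "try-error") || inherits(b, "error"))
        stop("FHIR page retrieval failed for ", type, call. = FALSE)
      bt <- b$total %||% NA_integer_
      if (!is.na(total) && !is.na(bt) && bt != total)
        warning(sprintf("inconsistent total for %s: first page said %d, later page %d",
                        type, total, bt), call. = FALSE)
      resources <- c(resources, unlist(lapply(b$entry %||% list(),
                                              function(e) list(e$resource)),
                                       recursive = FALSE))
    }
  }
  resources <- resources[!vapply(resources, is.null, logical(1))]
  # order-independent merge: dedupe by (type, id), sort by key
  keys <- vapply(resources, function(r)
    paste0(r$resourceType %||% "?", "/", r$id %||% ""), character(1))
  resources <- resources[!duplicated(keys)]
  resources <- resources[order(keys[!duplicated(keys)])]
  resources_to_dataset(resources, systems, item_catalog, provenance,
                       total_inpatient_cases)
}

http_fetcher <- function(url) {
  con <- url(url)
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}
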