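# Synthetic paired fixtures: terminology + CSV/NDJSON datasets with a
# planted-issue ledger, so every detector and both readers are testable
# offline against known ground truth.

#' Specify a synthetic fixture
#'
#' Describes a paired reference/degraded dataset with exact planted DQ
#' issues. Planted issues are mutually exclusive per record, which keeps
#' the ledger arithmetic exact; note the one structural coupling that
#' cannot be avoided: an ambiguous case planted through a multi-Orphacode
#' tracer without an Orphacode is, by definition, also a missing-Orphacode
#' issue, so the expected P10 is `missing_orphacodes + ambiguous_cases`.
#'
#' Defaults describe a small ward-scale extract: 40 patients with 60
#' inpatient cases in the 2021 study year, a terminology with 8
#' single-Orphacode tracer codes, 2 multi-Orphacode tracer codes (the
#' ambiguity substrate) and 4 non-tracer codes (one term each lacking an
#' Orphacode), and a handful of planted issues per category.
#'
#' @param n_patients,n_cases positive integers.
#' @param terminology list(n_tracers, n_multi_orpha, n_non_tracers).
#' @param planted named list of planted-issue counts: missing_values,
#'   missing_items (0-3), outliers, missing_orphacodes, implausible_links,
#'   duplicates, ambiguous_cases.
#' @param degradation FAIRification-emulation switches applied to the
#'   second dataset: `drop_all_orphacodes` (the claims-data scenario in
#'   which Orphacodes never reach the transformed dataset),
#'   `drop_items` (field names blanked everywhere), `drop_case_fraction`
#'   (fraction of cases removed, from the end).
#' @param seed integer random seed; same seed + spec gives byte-identical
#'   outputs.
#' @return validated object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_patients = 40L, n_cases = 60L,
                         terminology = list(n_tracers = 8L, n_multi_orpha = 2L,
                                            n_non_tracers = 4L),
                         planted = list(missing_values = 5L, missing_items = 2L,
                                        outliers = 2L, missing_orphacodes = 4L,
                                        implausible_links = 2L, duplicates = 3L,
                                        ambiguous_cases = 2L),
                         degradation = list(drop_all_orphacodes = FALSE,
                                            drop_items = character(0),
                                            drop_case_fraction = 0),
                         seed = 1L) {
  defaults_p <- list(missing_values = 0L, missing_items = 0L, outliers = 0L,
                     missing_orphacodes = 0L, implausible_links = 0L,
                     duplicates = 0L, ambiguous_cases = 0L)
  planted <- utils::modifyList(defaults_p, as.list(planted))
  defaults_d <- list(drop_all_orphacodes = FALSE, drop_items = character(0),
                     drop_case_fraction = 0)
  degradation <- utils::modifyList(defaults_d, as.list(degradation))
  defaults_t <- list(n_tracers = 0L, n_multi_orpha = 0L, n_non_tracers = 0L)
  terminology <- utils::modifyList(defaults_t, as.list(terminology))

  stopifnot(n_patients >= 1, n_cases >= 0, seed == as.integer(seed))
  if (any(unlist(planted) < 0) || any(unlist(terminology) < 0))
    stop("fixture_spec: counts must be non-negative", call. = FALSE)

  issue_cases <- planted$ambiguous_cases + planted$missing_orphacodes +
    planted$implausible_links + planted$outliers
  clean <- n_cases - issue_cases
  n_pat_eff <- min(n_patients, max(n_cases, 0L))
  # value plants must never empty an item outright (that would be an
  # item-level, not value-level, issue): keep >= 1 value per planted field
  diag_cap <- clean - planted$duplicates
  if (issue_cases + planted$duplicates == 0) diag_cap <- max(0L, diag_cap - 1L)
  sex_cap <- max(0L, n_pat_eff - 1L)
  binding <- NULL
  if (clean < 0)
    binding <- sprintf("ambiguous+missing_orphacodes+implausible+outliers = %d exceeds n_cases = %d",
                       issue_cases, n_cases)
  else if (planted$duplicates > clean)
    binding <- sprintf("duplicates = %d exceeds clean cases = %d",
                       planted$duplicates, clean)
  else if (planted$missing_values > diag_cap + sex_cap)
    binding <- sprintf("missing_values = %d exceeds capacity = %d (plantable diagnosis dates + patient sex values)",
                       planted$missing_values, diag_cap + sex_cap)
  else if (planted$missing_items > 3)
    binding <- "missing_items exceeds the 3 droppable items (address_city, address_postal_code, diagnosis_role)"
  else if (planted$ambiguous_cases > 0 && terminology$n_multi_orpha < 1)
    binding <- "ambiguous_cases > 0 requires n_multi_orpha >= 1"
  else if (n_cases > 0 && terminology$n_tracers + terminology$n_multi_orpha < 1)
    binding <- "cases require at least one tracer code in the terminology"
  if (!is.null(binding))
    stop("fixture_spec unsatisfiable: ", binding, call. = FALSE)

  structure(list(n_patients = as.integer(n_patients),
                 n_cases = as.integer(n_cases), terminology = terminology,
                 planted = planted, degradation = degradation,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic Alpha-ID-SE-style terminology
#'
#' Emits a terminology that parses under the default dialect and whose
#' derived tracer set equals the planted ground truth by construction:
#' single-Orphacode tracer codes (two terms, one shared Orphacode),
#' multi-Orphacode tracer codes (two terms, two distinct Orphacodes — the
#' ambiguity substrate), and non-tracer codes (one term lacking an
#' Orphacode).
#'
#' @param spec a `fixture_spec`.
#' @param path optional file to write the terminology lines to.
#' @return list with `terminology` (parsed `alpha_terminology`), `lines`,
#'   `tracers` (ground-truth `tracer_set`), and the code groups
#'   `tracer_codes`, `multi_codes`, `non_tracer_codes`, plus
#'   `code_orphas` (list: code -> its Orphacodes).
#' @export
gen_terminology <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  ts <- spec$terminology
  n_codes <- ts$n_tracers + ts$n_multi_orpha + ts$n_non_tracers
  codes <- character(0)
  while (length(codes) < n_codes) {
    cand <- paste0(sample(LETTERS, 1), sprintf("%02d", sample(0:99, 1)), ".",
                   sample(0:9, 1))
    if (!cand %in% codes) codes <- c(codes, cand)
  }
  tracer_codes <- codes[seq_len(ts$n_tracers)]
  multi_codes <- codes[ts$n_tracers + seq_len(ts$n_multi_orpha)]
  non_tracer_codes <- codes[ts$n_tracers + ts$n_multi_orpha +
                              seq_len(ts$n_non_tracers)]
  orpha_next <- 1000L
  aid_next <- 1L
  lines <- character(0)
  code_orphas <- list()
  emit <- function(icd, orpha, label) {
    aid <- sprintf("I%06d", aid_next)
    aid_next <<- aid_next + 1L
    lines <<- c(lines, paste("1", aid, icd, "", "",
                             if (is.na(orpha)) "" else orpha, label, sep = "|"))
  }
  for (c in tracer_codes) {
    o <- orpha_next; orpha_next <- orpha_next + 1L
    code_orphas[[c]] <- o
    emit(c, o, paste("Disorder", c, "term A"))
    emit(c, o, paste("Disorder", c, "term B"))
  }
  for (c in multi_codes) {
    o1 <- orpha_next; o2 <- orpha_next + 1L; orpha_next <- orpha_next + 2L
    code_orphas[[c]] <- c(o1, o2)
    emit(c, o1, paste("Disorder", c, "variant 1"))
    emit(c, o2, paste("Disorder", c, "variant 2"))
  }
  for (c in non_tracer_codes) {
    o <- orpha_next; orpha_next <- orpha_next + 1L
    code_orphas[[c]] <- o
    emit(c, o, paste("Disorder", c, "rare term"))
    emit(c, NA, paste("Disorder", c, "unannotated term"))
  }
  if (!is.null(path)) writeLines(lines, path)
  term <- parse_alpha_id_se(lines)
  list(terminology = term, lines = lines,
       tracers = tracer_set(c(tracer_codes, multi_codes), "alpha_derived"),
       tracer_codes = tracer_codes, multi_codes = multi_codes,
       non_tracer_codes = non_tracer_codes, code_orphas = code_orphas,
       next_orpha = orpha_next)
}

#' Generate a paired reference/degraded dataset with a planted ledger
#'
#' Builds the reference dataset containing exactly the planted issues of
#' `spec`, applies the degradation switches to produce the transformed
#' dataset, and writes both in the two interchange shapes (PAS-style CSV
#' and FHIR-style NDJSON) from the one ledger. The ledger carries the
#' expected full parameter set for both datasets (computed by an
#' independent plain-loop recount, cross-checked against the planted
#' arithmetic) and the expected loss vector of the pair.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir optional directory; when given, writes
#'   `terminology.txt`, `reference.csv`, `degraded.csv`,
#'   `<dataset>_<Type>.ndjson` files and `ledger.json`.
#' @return list with `reference` and `degraded` (`case_dataset`s),
#'   `terminology`, `tracers`, `ledger`, and `files` (named paths or
#'   `NULL`).
#' @export
gen_dataset_pair <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  tg <- gen_terminology(spec)   # seeds the RNG from spec$seed
  n <- spec$n_cases
  pl <- spec$planted

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(spec$n_patients)),
    birth_date = as.character(as.Date("1930-01-01") +
                                sample(0:29219, spec$n_patients, replace = TRUE)),
    sex = sample(c("male", "female"), spec$n_patients, replace = TRUE),
    address_city = sample(c("Nordstadt", "Suedheim", "Osterberg", "Westtal"),
                          spec$n_patients, replace = TRUE),
    address_postal_code = sprintf("%05d", sample(10000:99999, spec$n_patients)),
    stringsAsFactors = FALSE)

  # every patient must be referenced by a case so both renderings carry
  # the same patient set
  patients <- utils::head(patients, min(spec$n_patients, n))

  adm <- as.Date("2021-01-01") + sample(0:330, n, replace = TRUE)
  encounters <- data.frame(
    case_id = sprintf("C%05d", seq_len(n)),
    patient_id = rep(patients$patient_id, length.out = n),
    admission_date = as.character(adm),
    discharge_date = as.character(adm + sample(1:14, n, replace = TRUE)),
    encounter_class = rep("IMP", n), stringsAsFactors = FALSE)

  # role layout: ambiguous | missing orpha | implausible | outlier | clean
  i_amb <- seq_len(pl$ambiguous_cases)
  i_mo <- pl$ambiguous_cases + seq_len(pl$missing_orphacodes)
  i_il <- pl$ambiguous_cases + pl$missing_orphacodes + seq_len(pl$implausible_links)
  i_ol <- pl$ambiguous_cases + pl$missing_orphacodes + pl$implausible_links +
    seq_len(pl$outliers)
  i_clean <- setdiff(seq_len(n), c(i_amb, i_mo, i_il, i_ol))

  pick <- function(pool, k) pool[(seq_len(k) - 1L) %% length(pool) + 1L]
  icd <- character(n); orpha <- rep(NA_integer_, n)
  if (length(i_amb) > 0) icd[i_amb] <- pick(tg$multi_codes, length(i_amb))
  if (length(i_mo) > 0) icd[i_mo] <- pick(tg$tracer_codes, length(i_mo))
  if (length(i_il) > 0) {
    icd[i_il] <- pick(tg$tracer_codes, length(i_il))
    orpha[i_il] <- tg$next_orpha + seq_along(i_il)   # absent from terminology
  }
  clean_like <- c(i_ol, i_clean)
  if (length(clean_like) > 0) {
    use_non <- length(tg$non_tracer_codes) > 0 &
      (seq_along(clean_like) %% 3L == 0L)
    pool_t <- c(tg$tracer_codes, tg$multi_codes)
    icd[clean_like[!use_non]] <- pick(pool_t, sum(!use_non))
    if (any(use_non))
      icd[clean_like[use_non]] <- pick(tg$non_tracer_codes, sum(use_non))
    orpha[clean_like] <- vapply(icd[clean_like], function(c)
      as.integer(tg$code_orphas[[c]][1]), integer(1))
  }
  # outlier plant: discharge precedes admission
  if (length(i_ol) > 0)
    encounters$discharge_date[i_ol] <-
      as.character(parse_day_date(encounters$admission_date[i_ol]) -
                     sample(1:5, length(i_ol), replace = TRUE))

  diagnoses <- data.frame(
    condition_id = sprintf("D%05d", seq_len(n)),
    case_id = encounters$case_id,
    patient_id = encounters$patient_id,
    icd_code = icd, orphacode = orpha,
    diagnosis_date = encounters$admission_date,
    role = rep("primary", n), stringsAsFactors = FALSE)

  # duplicates: copy the first planted$duplicates clean diagnoses
  i_dup_src <- i_clean[seq_len(pl$duplicates)]
  if (pl$duplicates > 0) {
    dup <- diagnoses[i_dup_src, , drop = FALSE]
    dup$condition_id <- sprintf("DDUP%04d", seq_len(pl$duplicates))
    diagnoses <- rbind(diagnoses, dup)
  }

  # missing values: diagnosis dates of clean non-duplicated cases first,
  # then patient sex
  avail <- setdiff(i_clean, i_dup_src)
  mv_diag <- utils::head(avail, pl$missing_values)
  diagnoses$diagnosis_date[mv_diag] <- NA_character_
  mv_left <- pl$missing_values - length(mv_diag)
  if (mv_left > 0) patients$sex[seq_len(mv_left)] <- NA_character_

  # missing items: blank a field everywhere
  droppable <- c("address_city", "address_postal_code", "diagnosis_role")
  dropped <- utils::head(droppable, pl$missing_items)
  if ("address_city" %in% dropped) patients$address_city <- NA_character_
  if ("address_postal_code" %in% dropped)
    patients$address_postal_code <- NA_character_
  if ("diagnosis_role" %in% dropped) diagnoses$role <- NA_character_

  reference <- list(patients = patients, encounters = encounters,
                    diagnoses = diagnoses)
  degraded <- degrade_records(reference, spec$degradation)

  link_pairs <- tg$terminology$link_set
  multi_set <- tg$multi_codes
  tracer_set_codes <- tg$tracers$codes

  exp_ref <- recount_params(reference, tracer_set_codes, multi_set, link_pairs)
  exp_deg <- recount_params(degraded, tracer_set_codes, multi_set, link_pairs)

  # cross-check the recount against the planted arithmetic
  check <- c(im_misg = pl$missing_items, vm_misg = pl$missing_values,
             vo = pl$outliers,
             oc_misg = pl$missing_orphacodes + pl$ambiguous_cases,
             link_ip = pl$implausible_links, rdCase_dup = pl$duplicates,
             rdCase_amb = pl$ambiguous_cases)
  got <- unlist(exp_ref[names(check)])
  if (!identical(unname(got), unname(as.numeric(check))) &&
      !all(got == check))
    stop("internal fixture error: recount disagrees with planted arithmetic (",
         paste(sprintf("%s: %s != %s", names(check), got, check),
               collapse = "; "), ")", call. = FALSE)

  expected_lost <- expected_lost_vector(exp_ref, exp_deg)
  ledger <- list(
    spec = unclass(spec), planted = pl,
    ids = list(ambiguous_cases = encounters$case_id[i_amb],
               missing_orphacodes = diagnoses$condition_id[i_mo],
               implausible_links = diagnoses$condition_id[i_il],
               outliers = encounters$case_id[i_ol],
               duplicates = if (pl$duplicates > 0)
                 sprintf("DDUP%04d", seq_len(pl$duplicates)) else character(0),
               missing_value_records = c(diagnoses$condition_id[mv_diag],
                                         if (mv_left > 0)
                                           patients$patient_id[seq_len(mv_left)]
                                         else character(0)),
               missing_items = dropped),
    expected = list(reference = exp_ref, degraded = exp_deg),
    expected_lost = expected_lost)

  ref_ds <- case_dataset(patients, encounters, diagnoses, provenance = "EXP")
  deg_ds <- case_dataset(degraded$patients, degraded$encounters,
                         degraded$diagnoses, provenance = "FHIR")

  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(terminology = file.path(out_dir, "terminology.txt"))
    writeLines(tg$lines, files[["terminology"]])
    for (nm in c("reference", "degraded")) {
      ds <- if (nm == "reference") ref_ds else deg_ds
      f_csv <- file.path(out_dir, paste0(nm, ".csv"))
      write_pas_csv(ds, f_csv)
      files[paste0(nm, "_csv")] <- f_csv
      nd <- write_fixture_ndjson(ds, out_dir, nm)
      files[names(nd)] <- nd
    }
    files["ledger"] <- file.path(out_dir, "ledger.json")
    jsonlite::write_json(ledger, files[["ledger"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  list(reference = ref_ds, degraded = deg_ds, terminology = tg$terminology,
       tracers = tg$tracers, ledger = ledger, files = files)
}

degrade_records <- function(recs, degradation) {
  p <- recs$patients; e <- recs$encounters; d <- recs$diagnoses
  if (isTRUE(degradation$drop_all_orphacodes)) d$orphacode <- NA_integer_
  for (f in degradation$drop_items %||% character(0)) {
    if (f %in% names(p)) p[[f]] <- NA_character_
    if (f %in% names(e)) e[[f]] <- NA_character_
    if (f %in% names(d) && f != "orphacode") d[[f]] <- NA_character_
  }
  frac <- degradation$drop_case_fraction %||% 0
  if (frac > 0) {
    n_drop <- ceiling(frac * nrow(e))
    keep_cases <- utils::head(e$case_id, nrow(e) - n_drop)
    e <- e[e$case_id %in% keep_cases, , drop = FALSE]
    d <- d[d$case_id %in% keep_cases, , drop = FALSE]
    p <- p[p$patient_id %in% e$patient_id, , drop = FALSE]
  }
  rownames(p) <- rownames(e) <- rownames(d) <- NULL
  list(patients = p, encounters = e, diagnoses = d)
}

# Independent plain-loop recount of all parameters and denominators; the
# ledger oracle against which the engine is checked.
recount_params <- function(recs, tracer_codes, multi_codes, link_pairs) {
  p <- recs$patients; e <- recs$encounters; d <- recs$diagnoses
  catalog <- default_item_catalog()
  rec_of <- function(t) switch(t, patient = p, encounter = e, diagnosis = d)

  orpha_cases <- character(0); tracer_cases <- character(0)
  for (i in seq_len(nrow(d))) {
    if (!is.na(d$orphacode[i])) orpha_cases <- union(orpha_cases, d$case_id[i])
    if (!is.na(d$icd_code[i]) && d$icd_code[i] %in% tracer_codes)
      tracer_cases <- union(tracer_cases, d$case_id[i])
  }
  rd_cases <- union(orpha_cases, tracer_cases)

  present <- logical(nrow(catalog)); names(present) <- catalog$item
  for (i in seq_len(nrow(catalog))) {
    rec <- rec_of(catalog$record_type[i]); f <- catalog$field[i]
    pres <- FALSE
    for (r in seq_len(nrow(rec)))
      if (!is.na(rec[[f]][r]) && nzchar(as.character(rec[[f]][r]))) {
        pres <- TRUE; break
      }
    present[i] <- pres
  }
  p7 <- sum(!present)

  p8 <- 0L; slots <- 0L
  for (i in which(present)) {
    rec <- rec_of(catalog$record_type[i]); f <- catalog$field[i]
    slots <- slots + nrow(rec)
    for (r in seq_len(nrow(rec)))
      if (is.na(rec[[f]][r]) || !nzchar(as.character(rec[[f]][r])))
        p8 <- p8 + 1L
  }

  p9 <- 0L; checked <- 0L
  for (r in seq_len(nrow(e))) {
    b <- p$birth_date[match(e$patient_id[r], p$patient_id)]
    adm <- parse_day_date(e$admission_date[r])
    dis <- parse_day_date(e$discharge_date[r])
    if (!is.na(adm) && length(b) == 1 && !is.na(b)) {
      bd <- parse_day_date(b)
      if (!is.na(bd)) {
        checked <- checked + 1L
        if (as.numeric(adm - bd) / 365.25 > 130) p9 <- p9 + 1L
      }
    }
    if (!is.na(adm) && !is.na(dis)) {
      checked <- checked + 1L
      if (dis < adm) p9 <- p9 + 1L
    }
  }
  for (r in seq_len(nrow(d)))
    if (!is.na(d$icd_code[r])) {
      checked <- checked + 1L
      if (grepl("[^A-Z0-9.]", d$icd_code[r])) p9 <- p9 + 1L
    }

  p10 <- 0L; n_tracer_diag <- 0L
  for (r in seq_len(nrow(d)))
    if (!is.na(d$icd_code[r]) && d$icd_code[r] %in% tracer_codes) {
      n_tracer_diag <- n_tracer_diag + 1L
      if (is.na(d$orphacode[r])) p10 <- p10 + 1L
    }

  p11 <- 0L; n_linked <- 0L
  for (r in seq_len(nrow(d)))
    if (!is.na(d$icd_code[r]) && !is.na(d$orphacode[r])) {
      n_linked <- n_linked + 1L
      if (!paste0(d$icd_code[r], "|", d$orphacode[r]) %in% link_pairs)
        p11 <- p11 + 1L
    }

  keys <- character(0); p12 <- 0L
  for (r in seq_len(nrow(d))) {
    k <- paste(d$case_id[r], d$patient_id[r], d$icd_code[r],
               ifelse(is.na(d$orphacode[r]), "-", d$orphacode[r]), sep = "\r")
    if (k %in% keys) p12 <- p12 + 1L else keys <- c(keys, k)
  }

  amb_cases <- character(0)
  for (r in seq_len(nrow(d))) {
    if (is.na(d$icd_code[r]) || !d$icd_code[r] %in% multi_codes) next
    if (!d$case_id[r] %in% rd_cases) next
    if (is.na(d$orphacode[r]))
      amb_cases <- union(amb_cases, d$case_id[r])
    else if (!paste0(d$icd_code[r], "|", d$orphacode[r]) %in% link_pairs)
      amb_cases <- union(amb_cases, d$case_id[r])
  }

  list(rdCase = length(rd_cases), orphaCase = length(orpha_cases),
       tracerCase = length(tracer_cases), im_misg = p7, vm_misg = p8,
       vo = p9, oc_misg = p10, link_ip = p11, rdCase_dup = p12,
       rdCase_amb = length(amb_cases), n_items = nrow(catalog),
       n_value_slots = slots, n_checked_values = checked,
       n_tracer_diagnoses = n_tracer_diag, n_linked_diagnoses = n_linked,
       n_case_records = nrow(d))
}

expected_lost_vector <- function(exp_ref, exp_deg) {
  nm <- c("rdCase", "orphaCase", "tracerCase", "rdCase_rel", "orphaCase_rel",
          "tracerCase_rel", "im_misg", "vm_misg", "vo", "oc_misg", "link_ip",
          "rdCase_dup", "rdCase_amb")
  lost <- vapply(seq_along(nm), function(i) {
    a <- exp_ref[[nm[i]]]; b <- exp_deg[[nm[i]]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    if (i %in% c(7, 8, 9)) b - a else a - b
  }, numeric(1))
  data.frame(i = seq_along(nm), parameter = nm, lost = lost,
             stringsAsFactors = FALSE)
}

# NDJSON rendering of a case_dataset, one resource per line, resources in
# record order so both readers reconstruct identical datasets.
write_fixture_ndjson <- function(ds, out_dir, prefix) {
  json1 <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                        na = "null", digits = NA)
  drop_na <- function(l) l[!vapply(l, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  sys <- fhir_systems()

  p_lines <- vapply(seq_len(nrow(ds$patients)), function(i) {
    p <- ds$patients[i, ]
    addr <- drop_na(list(city = p$address_city,
                         postalCode = p$address_postal_code))
    res <- drop_na(list(resourceType = "Patient", id = p$patient_id,
                        birthDate = p$birth_date, gender = p$sex))
    if (length(addr) > 0) res$address <- list(addr)
    as.character(json1(res))
  }, character(1))

  e_lines <- vapply(seq_len(nrow(ds$encounters)), function(i) {
    e <- ds$encounters[i, ]
    res <- drop_na(list(resourceType = "Encounter", id = e$case_id))
    res$subject <- list(reference = paste0("Patient/", e$patient_id))
    period <- drop_na(list(start = e$admission_date, end = e$discharge_date))
    if (length(period) > 0) res$period <- period
    if (!is.na(e$encounter_class)) res$class <- list(code = e$encounter_class)
    as.character(json1(res))
  }, character(1))

  d_lines <- vapply(seq_len(nrow(ds$diagnoses)), function(i) {
    d <- ds$diagnoses[i, ]
    res <- drop_na(list(resourceType = "Condition", id = d$condition_id))
    res$subject <- list(reference = paste0("Patient/", d$patient_id))
    res$encounter <- list(reference = paste0("Encounter/", d$case_id))
    codings <- list()
    if (!is.na(d$icd_code))
      codings <- c(codings, list(list(system = sys$icd, code = d$icd_code)))
    if (!is.na(d$orphacode))
      codings <- c(codings, list(list(system = sys$orpha,
                                      code = as.character(d$orphacode))))
    if (length(codings) > 0) res$code <- list(coding = codings)
    if (!is.na(d$diagnosis_date)) res$onsetDateTime <- d$diagnosis_date
    if (!is.na(d$role))
      res$category <- list(list(coding = list(list(code = d$role))))
    as.character(json1(res))
  }, character(1))

  files <- c(file.path(out_dir, paste0(prefix, "_Patient.ndjson")),
             file.path(out_dir, paste0(prefix, "_Encounter.ndjson")),
             file.path(out_dir, paste0(prefix, "_Condition.ndjson")))
  names(files) <- paste0(prefix, c("_patient_ndjson", "_encounter_ndjson",
                                   "_condition_ndjson"))
  writeLines(p_lines, files[[1]])
  writeLines(e_lines, files[[2]])
  writeLines(d_lines, files[[3]])
  files
}
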