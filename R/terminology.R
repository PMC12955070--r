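# Alpha-ID-SE-style terminology: parsing, tracer derivation, link queries.

#' Normalize ICD-10-GM codes
#'
#' Uppercases, trims whitespace and strips the trailing usage markers
#' (`!`, `+`, `*`) that German coding practice appends to secondary and
#' cross-referenced codes, so that codes compare equal across CSV and FHIR
#' sources. The stripped marker is available via [icd_marker()].
#'
#' @param x character vector of raw ICD-10-GM codes.
#' @return character vector of normalized codes (`NA` stays `NA`).
#' @examples
#' icd_normalize(c("e84.0", " G71.2+ ", "M90.4*"))
#' @export
icd_normalize <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!is.na(x) & x == ""] <- NA_character_
  sub("[!+*]+$", "", x)
}

#' @rdname icd_normalize
#' @return `icd_marker()` returns the trailing marker (`""` when none).
#' @export
icd_marker <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexpr("[!+*]+$", x))
  out <- character(length(x))
  out[regexpr("[!+*]+$", x) > 0] <- m
  out[is.na(x)] <- NA_character_
  out
}

#' Validate ICD-10-GM code syntax
#'
#' A well-formed code is a letter, two digits, and optionally a dot followed
#' by one or two alphanumerics (e.g. `"Q87.5"`, `"E84.0"`, `"A01"`).
#'
#' @param x character vector of normalized codes.
#' @return logical vector; `NA` input gives `FALSE`.
#' @export
icd_is_valid <- function(x) {
  !is.na(x) & grepl("^[A-Z][0-9]{2}(\\.[A-Za-z0-9]{1,2})?$", x)
}

#' Normalize Orphacodes
#'
#' Strips an optional `"ORPHA:"`/`"Orpha:"` prefix and converts to integer.
#' Non-numeric remainders become `NA` (a value-level issue for the outlier
#' rules, never a load failure).
#'
#' @param x character or numeric vector.
#' @return integer vector with an attribute `n_invalid` counting values that
#'   failed to parse.
#' @export
orpha_normalize <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  x <- sub("^[Oo][Rr][Pp][Hh][Aa]\\s*:\\s*", "", x)
  ok <- grepl("^[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out[!is.na(out) & out <= 0] <- NA_integer_
  structure(out, n_invalid = sum(!is.na(x) & is.na(out)))
}

#' Default Alpha-ID-SE file dialect
#'
#' The terminology file is pipe-delimited; the dialect gives the 0-based
#' field position of each semantic field. The default order is
#' `validity|alpha_id|icd_primary|icd_star|additional|orphacode|label`,
#' which tolerates year-to-year drift of the official releases through
#' reconfiguration rather than code changes.
#'
#' @param validity,alpha_id,icd_primary,icd_star,orphacode,label 0-based
#'   field positions.
#' @return a named list of class `"alpha_dialect"`.
#' @export
alpha_dialect <- function(validity = 0L, alpha_id = 1L, icd_primary = 2L,
                          icd_star = 3L, orphacode = 5L, label = 6L) {
  d <- list(validity = validity, alpha_id = alpha_id,
            icd_primary = icd_primary, icd_star = icd_star,
            orphacode = orphacode, label = label)
  if (anyDuplicated(unlist(d)))
    stop("alpha_dialect: field positions must be distinct", call. = FALSE)
  structure(d, class = "alpha_dialect")
}

#' Parse an Alpha-ID-SE-style terminology
#'
#' Reads a pipe-delimited terminology into an `alpha_terminology` object:
#' one entry per well-formed line, a link set of (ICD, Orphacode) pairs over
#' the valid entries, and a list of collected parse errors. Lines failing
#' the dialect are collected, never silently dropped; if more than half of
#' the non-empty lines are malformed the input is rejected as a format
#' error naming the first offending line.
#'
#' @param x a file path or a character vector of lines.
#' @param dialect field layout, see [alpha_dialect()].
#' @return an object of class `"alpha_terminology"` with elements
#'   `entries` (data.frame: alpha_id, valid, icd_primary, icd_marker,
#'   icd_star, orphacode, label) and `parse_errors` (data.frame: line,
#'   reason).
#' @examples
#' term <- parse_alpha_id_se("1|I128560|Q87.5||Q87.5|2097|Grant syndrome")
#' term$entries
#' @export
parse_alpha_id_se <- function(x, dialect = alpha_dialect()) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  nf <- max(unlist(dialect)) + 1L

  err_line <- integer(0); err_reason <- character(0)
  rows <- vector("list", n)
  seen_ids <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "|", fixed = TRUE)[[1]]
    if (length(f) < nf) {
      err_line <- c(err_line, i)
      err_reason <- c(err_reason, sprintf("expected >= %d fields, got %d", nf, length(f)))
      next
    }
    pick <- function(pos) trimws(f[[pos + 1L]])
    aid <- pick(dialect$alpha_id)
    icd_raw <- pick(dialect$icd_primary)
    icd <- icd_normalize(icd_raw)
    orpha_raw <- pick(dialect$orphacode)
    if (!nzchar(aid)) {
      err_line <- c(err_line, i); err_reason <- c(err_reason, "empty alpha_id"); next
    }
    if (!is.null(seen_ids[[aid]])) {
      err_line <- c(err_line, i)
      err_reason <- c(err_reason, sprintf("duplicate alpha_id '%s'", aid)); next
    }
    if (is.na(icd) || !icd_is_valid(icd)) {
      err_line <- c(err_line, i)
      err_reason <- c(err_reason, sprintf("invalid ICD-10-GM code '%s'", icd_raw)); next
    }
    orpha <- NA_integer_
    if (nzchar(orpha_raw)) {
      orpha <- orpha_normalize(orpha_raw)[[1]]
      if (is.na(orpha)) {
        err_line <- c(err_line, i)
        err_reason <- c(err_reason, sprintf("invalid Orphacode '%s'", orpha_raw)); next
      }
    }
    seen_ids[[aid]] <- TRUE
    star <- icd_normalize(pick(dialect$icd_star))
    rows[[i]] <- data.frame(
      alpha_id = aid,
      valid = pick(dialect$validity) == "1",
      icd_primary = icd,
      icd_marker = icd_marker(icd_raw),
      icd_star = if (is.na(star) || !nzchar(star)) NA_character_ else star,
      orphacode = orpha,
      label = pick(dialect$label),
      stringsAsFactors = FALSE
    )
  }

  if (n > 0 && length(err_line) > n / 2)
    stop(sprintf("terminology format error: %d of %d lines malformed (first at line %d: %s)",
                 length(err_line), n, err_line[[1]], err_reason[[1]]), call. = FALSE)

  entries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(entries))
    entries <- data.frame(alpha_id = character(0), valid = logical(0),
                          icd_primary = character(0), icd_marker = character(0),
                          icd_star = character(0), orphacode = integer(0),
                          label = character(0), stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new_alpha_terminology(entries,
                        data.frame(line = err_line, reason = err_reason,
                                   stringsAsFactors = FALSE),
                        dialect)
}

new_alpha_terminology <- function(entries, parse_errors, dialect) {
  v <- entries[entries$valid & !is.na(entries$orphacode), , drop = FALSE]
  structure(list(
    entries = entries,
    parse_errors = parse_errors,
    dialect = dialect,
    link_set = unique(paste0(v$icd_primary, "|", v$orphacode))
  ), class = "alpha_terminology")
}

#' @export
print.alpha_terminology <- function(x, ...) {
  cat(sprintf("Alpha-ID-SE-style terminology: %d entries (%d valid), %d ICD codes, %d parse errors\n",
              nrow(x$entries), sum(x$entries$valid),
              length(unique(x$entries$icd_primary)), nrow(x$parse_errors)))
  invisible(x)
}

#' Serialize a terminology back to its file dialect
#'
#' Inverse of [parse_alpha_id_se()]: re-parsing the output yields an
#' identical entry set (parse errors are not round-tripped).
#'
#' @param term an `alpha_terminology`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
write_alpha_id_se <- function(term, path = NULL) {
  stopifnot(inherits(term, "alpha_terminology"))
  d <- term$dialect
  nf <- max(unlist(d)) + 1L
  e <- term$entries
  lines <- vapply(seq_len(nrow(e)), function(i) {
    f <- rep("", nf)
    f[d$validity + 1L] <- if (e$valid[i]) "1" else "0"
    f[d$alpha_id + 1L] <- e$alpha_id[i]
    f[d$icd_primary + 1L] <- paste0(e$icd_primary[i],
                                    if (is.na(e$icd_marker[i])) "" else e$icd_marker[i])
    f[d$icd_star + 1L] <- if (is.na(e$icd_star[i])) "" else e$icd_star[i]
    f[d$orphacode + 1L] <- if (is.na(e$orphacode[i])) "" else as.character(e$orphacode[i])
    f[d$label + 1L] <- e$label[i]
    paste(f, collapse = "|")
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Derive the Alpha-ID-SE tracer diagnosis set
#'
#' A tracer diagnosis is an ICD-10-GM code that exclusively codes rare
#' diseases: every valid diagnostic term carrying the code also carries an
#' Orphacode. Codes with zero valid entries are not tracers; invalid
#' (retired) entries are ignored.
#'
#' @param term an `alpha_terminology`.
#' @return a `tracer_set` (sorted unique codes, provenance
#'   `"alpha_derived"`).
#' @export
derive_tracers <- function(term) {
  stopifnot(inherits(term, "alpha_terminology"))
  e <- term$entries[term$entries$valid, , drop = FALSE]
  if (nrow(e) == 0) return(tracer_set(character(0), "alpha_derived"))
  all_orpha <- tapply(!is.na(e$orphacode), e$icd_primary, all)
  tracer_set(names(all_orpha)[all_orpha], "alpha_derived")
}

#' Construct a tracer set
#'
#' @param codes character vector of ICD-10-GM codes (normalized, deduplicated,
#'   sorted on construction).
#' @param provenance `"alpha_derived"` or `"curated"`.
#' @return an object of class `"tracer_set"`.
#' @export
tracer_set <- function(codes, provenance = c("alpha_derived", "curated")) {
  provenance <- match.arg(provenance)
  structure(list(codes = sort(unique(icd_normalize(codes))),
                 provenance = provenance),
            class = "tracer_set")
}

#' @export
print.tracer_set <- function(x, ...) {
  cat(sprintf("Tracer set (%s): %d ICD-10-GM codes\n", x$provenance,
              length(x$codes)))
  invisible(x)
}

#' Load a curated tracer list
#'
#' One ICD-10-GM code per line; `#` starts a comment. Codes are normalized
#' and deduplicated; tokens failing the ICD pattern are excluded with a
#' warning and counted in the `n_invalid` attribute.
#'
#' @param x file path or character vector of lines.
#' @return a `tracer_set` with provenance `"curated"`.
#' @export
load_curated_tracers <- function(x) {
  lines <- read_input_lines(x)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  codes <- icd_normalize(lines)
  ok <- icd_is_valid(codes)
  if (any(!ok))
    warning(sprintf("%d curated tracer token(s) failed ICD-10-GM validation and were excluded",
                    sum(!ok)), call. = FALSE)
  ts <- tracer_set(codes[ok], "curated")
  attr(ts, "n_invalid") <- sum(!ok)
  ts
}

#' Check the plausibility of an ICD-10-GM/Orphacode link
#'
#' A pair is plausible iff some valid terminology entry carries exactly that
#' (ICD, Orphacode) combination.
#'
#' @param term an `alpha_terminology`.
#' @param icd character vector of normalized ICD-10-GM codes.
#' @param orpha integer vector of Orphacodes (recycled pairwise with `icd`).
#' @return character vector, `"plausible"` or `"implausible"`.
#' @examples
#' term <- parse_alpha_id_se("1|I128560|Q87.5||Q87.5|2097|Grant syndrome")
#' check_link(term, "Q87.5", 2097)
#' check_link(term, "G71.2", 777)
#' @export
check_link <- function(term, icd, orpha) {
  stopifnot(inherits(term, "alpha_terminology"))
  icd <- icd_normalize(icd)
  orpha <- as.integer(orpha)
  n <- max(length(icd), length(orpha))
  if (n == 0) return(character(0))
  ifelse(paste0(rep_len(icd, n), "|", rep_len(orpha, n)) %in% term$link_set,
         "plausible", "implausible")
}

#' Orphacode candidates of an ICD-10-GM code
#'
#' All distinct Orphacodes attached to valid entries carrying the code. An
#' empty result means the code cannot be Orphacoded through this
#' terminology; more than one candidate marks an ambiguity substrate.
#'
#' @param term an `alpha_terminology`.
#' @param icd a single ICD-10-GM code.
#' @return sorted integer vector (possibly empty).
#' @export
orpha_candidates <- function(term, icd) {
  stopifnot(inherits(term, "alpha_terminology"))
  icd <- icd_normalize(icd)
  e <- term$entries
  sort(unique(e$orphacode[e$valid & e$icd_primary == icd & !is.na(e$orphacode)]))
}

# Accept either a path or a character vector of lines.
read_input_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    return(tryCatch(suppressWarnings(readLines(x, warn = FALSE)),
                    error = function(e) stop("cannot read '", x, "': ",
                                             conditionMessage(e), call. = FALSE)))
  }
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}
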