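# Two-sheet DQ report: SpreadsheetML workbook + deterministic CSV fallback.

#' Group issues for k-anonymized reporting
#'
#' Issues are grouped by (category, group key); a group whose affected
#' distinct-patient count is below `k` is suppressed and folded into one
#' aggregate `"suppressed (<k)"` row per category, so that no disclosed row
#' describes fewer than k patients. `k = 1` disables suppression.
#'
#' @param issues issue data.frame as produced by [dq_assess()].
#' @param k anonymity threshold (>= 1).
#' @return data.frame with columns `category`, `group_key`, `n_issues`,
#'   `n_patients` (`NA` on aggregate rows), `example_detail`.
#' @export
group_issues <- function(issues, k = 5L) {
  stopifnot(k >= 1)
  if (nrow(issues) == 0)
    return(data.frame(category = character(0), group_key = character(0),
                      n_issues = integer(0), n_patients = integer(0),
                      example_detail = character(0), stringsAsFactors = FALSE))
  key <- paste(issues$category, issues$group_key, sep = "\r")
  split_idx <- split(seq_len(nrow(issues)), key)
  grp <- do.call(rbind, lapply(split_idx, function(ix) {
    pats <- unique(issues$patient_id[ix])
    pats <- pats[!is.na(pats)]
    data.frame(category = issues$category[ix[1]],
               group_key = issues$group_key[ix[1]],
               n_issues = length(ix), n_patients = length(pats),
               example_detail = issues$detail[ix[1]],
               stringsAsFactors = FALSE)
  }))
  grp <- grp[order(grp$category, grp$group_key), , drop = FALSE]
  rownames(grp) <- NULL
  if (k == 1L) return(grp)
  # item-level rows have no patient locus and disclose nothing per patient
  suppress <- grp$n_patients < k & grp$category != "missing_item"
  keep <- grp[!suppress, , drop = FALSE]
  if (any(suppress)) {
    agg <- do.call(rbind, lapply(split(which(suppress), grp$category[suppress]),
                                 function(ix) data.frame(
      category = grp$category[ix[1]], group_key = sprintf("suppressed (<%d)", k),
      n_issues = sum(grp$n_issues[ix]), n_patients = NA_integer_,
      example_detail = sprintf("%d group(s) below the k-anonymity threshold",
                               length(ix)), stringsAsFactors = FALSE)))
    keep <- rbind(keep, agg)
    keep <- keep[order(keep$category, keep$group_key), , drop = FALSE]
  }
  rownames(keep) <- NULL
  keep
}

metrics_table <- function(params, indicators) {
  rows <- data.frame(
    section = "parameter",
    name = c(sprintf("P%d (%s)", seq_along(DQ_PARAM_NAMES), DQ_PARAM_NAMES)),
    value = vapply(DQ_PARAM_NAMES, function(n) {
      v <- params[[n]]
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1)),
    note = "", stringsAsFactors = FALSE)
  denoms <- c(n_items = "mandatory items", n_value_slots = "value slots",
              n_checked_values = "range-checked values",
              n_tracer_diagnoses = "tracer diagnoses",
              n_linked_diagnoses = "linked diagnoses",
              n_case_records = "case records")
  rows <- rbind(rows, data.frame(
    section = "denominator", name = unname(denoms),
    value = vapply(names(denoms), function(n) as.numeric(params[[n]]), numeric(1)),
    note = "", stringsAsFactors = FALSE))
  rows <- rbind(rows, data.frame(
    section = "indicator", name = indicators$indicator,
    value = round(indicators$value, 2),
    note = ifelse(indicators$vacuous, "vacuous denominator", ""),
    stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Write the DQ report files
#'
#' Writes a workbook (SpreadsheetML 2003 XML, openable in spreadsheet
#' applications) with the sheets \emph{DQ Metrics Report} (parameters,
#' denominators and indicators, one labeled row each) and \emph{DQ
#' Violations Report} (one row per k-anonymized issue group; see
#' [group_issues()]), plus a CSV fallback of every sheet. With a
#' `comparison`, a third sheet \emph{DQ Comparison Report} is added.
#' Output is deterministic: identical inputs yield byte-identical files.
#'
#' @param params a `dq_parameter_set`.
#' @param indicators a `dq_indicator_set`.
#' @param issues issue data.frame.
#' @param k anonymity threshold, default 5.
#' @param out output directory (created if needed).
#' @param comparison optional result of [dq_compare()].
#' @return named character vector of written file paths, invisibly.
#' @export
write_reports <- function(params, indicators, issues, k = 5L, out,
                          comparison = NULL) {
  stopifnot(k >= 1)
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory '", out, "'", call. = FALSE)
  metrics <- metrics_table(params, indicators)
  violations <- group_issues(issues, k)
  sheets <- list("DQ Metrics Report" = metrics,
                 "DQ Violations Report" = violations)
  files <- c(metrics = file.path(out, "dq_metrics_report.csv"),
             violations = file.path(out, "dq_violations_report.csv"))
  if (!is.null(comparison)) {
    comp <- as.data.frame(comparison$lost)
    sheets[["DQ Comparison Report"]] <- comp
    files <- c(files, comparison = file.path(out, "dq_comparison_report.csv"))
  }
  utils::write.csv(metrics, files[["metrics"]], row.names = FALSE, na = "")
  utils::write.csv(violations, files[["violations"]], row.names = FALSE, na = "")
  if (!is.null(comparison))
    utils::write.csv(sheets[["DQ Comparison Report"]], files[["comparison"]],
                     row.names = FALSE, na = "")
  wb <- file.path(out, "dq_report.xml")
  write_spreadsheetml(sheets, wb)
  files <- c(files, workbook = wb)
  invisible(files)
}

# Minimal SpreadsheetML 2003 serializer: plain-text XML workbook with named
# worksheets, sufficient for spreadsheet applications to open the report.
write_spreadsheetml <- function(sheets, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell <- function(v) {
    if (length(v) == 1 && (is.na(v) || (is.character(v) && !nzchar(v))))
      return("<Cell/>")
    type <- if (is.numeric(v)) "Number" else "String"
    sprintf("<Cell><Data ss:Type=\"%s\">%s</Data></Cell>", type,
            esc(as.character(v)))
  }
  lines <- c("<?xml version=\"1.0\"?>",
             "<?mso-application progid=\"Excel.Sheet\"?>",
             paste0("<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
                    " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">"))
  for (nm in names(sheets)) {
    df <- sheets[[nm]]
    lines <- c(lines, sprintf("<Worksheet ss:Name=\"%s\"><Table>", esc(nm)),
               paste0("<Row>", paste(vapply(names(df), cell, character(1)),
                                     collapse = ""), "</Row>"))
    for (r in seq_len(nrow(df)))
      lines <- c(lines, paste0("<Row>",
                               paste(vapply(seq_along(df), function(c)
                                 cell(df[r, c]), character(1)), collapse = ""),
                               "</Row>"))
    lines <- c(lines, "</Table></Worksheet>")
  }
  lines <- c(lines, "</Workbook>")
  writeLines(lines, path)
  invisible(path)
}
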