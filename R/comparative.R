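# Two-dataset comparison: per-parameter losses and their bookkeeping.

#' Per-parameter loss between a reference and a transformed dataset
#'
#' For two parameter sets computed from the same source — a reference
#' export and a transformed (FAIRified) dataset — the loss of parameter i
#' is defined piecewise: for the issue-count parameters i = 7, 8, 9
#' (missing items, missing values, outliers) it is
#' `Pi_transformed - Pi_reference`, because there more is worse; for every
#' other i in 1..13 it is `Pi_reference - Pi_transformed`, because there
#' the transformation can only lose observation units. Negative losses are
#' reported, never clamped: manual curation of claims data can genuinely
#' insert data.
#'
#' Positive losses are classified `"issue"`, except for i in {9, 12}
#' (outliers, duplicates) where a change may be intentional curation and
#' the classification is `"possibly-intentional"`; non-positive losses are
#' `"neutral"`. The relative parameters P4-P6 are compared only when both
#' totals are known and equal, otherwise they are `NA` with a warning.
#'
#' Both parameter sets must have been computed with the same item catalog,
#' tracer set and terminology; a fingerprint mismatch is a comparability
#' error.
#'
#' @param ref reference `dq_parameter_set` (e.g. the direct export).
#' @param transformed transformed `dq_parameter_set` (e.g. the FHIR
#'   rendering).
#' @return object of class `"dq_lost"`: data.frame with columns `i`,
#'   `parameter`, `p_ref`, `p_transformed`, `lost`, `sign_rule`,
#'   `classification`.
#' @examples
#' a <- dq_parameter_set(rdCase = 783, orphaCase = 729, tracerCase = 165)
#' b <- dq_parameter_set(rdCase = 163, orphaCase = 0, tracerCase = 163)
#' lost_parameters(a, b)
#' @export
lost_parameters <- function(ref, transformed) {
  stopifnot(inherits(ref, "dq_parameter_set"),
            inherits(transformed, "dq_parameter_set"))
  if (!is.null(ref$fingerprint) && !is.null(transformed$fingerprint) &&
      !identical(ref$fingerprint, transformed$fingerprint))
    stop("comparability error: parameter sets were computed with different ",
         "catalog/tracer/terminology configurations", call. = FALSE)

  rel <- 4:6
  totals_known <- !is.null(ref$total_inpatient_cases) &&
    !is.null(transformed$total_inpatient_cases)
  rel_ok <- totals_known &&
    ref$total_inpatient_cases == transformed$total_inpatient_cases
  if (totals_known && !rel_ok)
    warning("relative parameters P4-P6 not compared: differing inpatient totals",
            call. = FALSE)

  p_ref <- vapply(DQ_PARAM_NAMES, function(n)
    as.numeric(ref[[n]] %||% NA_real_), numeric(1))
  p_tr <- vapply(DQ_PARAM_NAMES, function(n)
    as.numeric(transformed[[n]] %||% NA_real_), numeric(1))
  i <- seq_along(DQ_PARAM_NAMES)
  inverted <- i %in% c(7, 8, 9)
  lost <- ifelse(inverted, p_tr - p_ref, p_ref - p_tr)
  lost[rel][!rel_ok] <- NA_real_

  classification <- rep("neutral", length(i))
  classification[!is.na(lost) & lost > 0] <- "issue"
  classification[i %in% c(9, 12) & !is.na(lost) & lost > 0] <- "possibly-intentional"

  out <- data.frame(
    i = i, parameter = DQ_PARAM_NAMES, p_ref = p_ref, p_transformed = p_tr,
    lost = lost,
    sign_rule = ifelse(inverted, "transformed-minus-reference",
                       "reference-minus-transformed"),
    classification = classification, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dq_lost", "data.frame")
  out
}

#' @export
print.dq_lost <- function(x, ...) {
  cat("Per-parameter losses (reference vs transformed):\n")
  for (j in seq_len(nrow(x))) {
    if (is.na(x$lost[j])) next
    cat(sprintf("  P%-2d %-15s ref=%-7s transformed=%-7s lost=%-7s [%s]\n",
                x$i[j], x$parameter[j], format(x$p_ref[j]),
                format(x$p_transformed[j]), format(x$lost[j]),
                x$classification[j]))
  }
  invisible(x)
}

#' Summarize the loss vector into issue totals
#'
#' The completeness-loss total sums the positive losses among the
#' completeness-bearing parameters: lost RD cases (P1), missing items (P7),
#' missing values (P8) and missing Orphacodes (P10). The grand
#' transformed-dataset issue total adds the transformed dataset's ambiguous
#' cases (P13) and the mandatory items missing in both datasets
#' (`min(P7_ref, P7_transformed)`), i.e. item gaps not attributable to the
#' transformation but still present in it.
#'
#' @param v a `dq_lost` object.
#' @return object of class `"dq_lost_summary"`: list with
#'   `completeness_loss_total`, `grand_total`, and a `breakdown`
#'   data.frame.
#' @export
summarize_lost <- function(v) {
  stopifnot(inherits(v, "dq_lost"))
  comp_idx <- c(1, 7, 8, 10)
  comp <- vapply(comp_idx, function(k) {
    l <- v$lost[v$i == k]
    if (is.na(l)) 0 else max(0, l)
  }, numeric(1))
  completeness_total <- sum(comp)
  amb_tr <- v$p_transformed[v$i == 13]
  shared_items <- min(v$p_ref[v$i == 7], v$p_transformed[v$i == 7])
  grand <- completeness_total + amb_tr + shared_items
  breakdown <- data.frame(
    component = c("lost RD cases (P1)", "missing items introduced (P7)",
                  "missing values introduced (P8)",
                  "missing Orphacodes introduced (P10)",
                  "completeness-loss total",
                  "ambiguous cases in transformed dataset (P13)",
                  "mandatory items missing in both datasets",
                  "grand issue total (transformed dataset)"),
    count = c(comp, completeness_total, amb_tr, shared_items, grand),
    stringsAsFactors = FALSE)
  structure(list(completeness_loss_total = completeness_total,
                 grand_total = grand, breakdown = breakdown),
            class = "dq_lost_summary")
}

#' @export
print.dq_lost_summary <- function(x, ...) {
  cat("Comparative DQ issue totals:\n")
  for (j in seq_len(nrow(x$breakdown)))
    cat(sprintf("  %-45s %s\n", x$breakdown$component[j],
                format(x$breakdown$count[j])))
  invisible(x)
}

#' Compare two assessed datasets end to end
#'
#' Convenience wrapper: takes two [dq_assess()] results, computes the loss
#' vector and its summary.
#'
#' @param ref,transformed `dq_assessment` objects.
#' @return list(lost, summary) of classes `dq_lost` / `dq_lost_summary`.
#' @export
dq_compare <- function(ref, transformed) {
  stopifnot(inherits(ref, "dq_assessment"), inherits(transformed, "dq_assessment"))
  lost <- lost_parameters(ref$params, transformed$params)
  list(lost = lost, summary = summarize_lost(lost))
}
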