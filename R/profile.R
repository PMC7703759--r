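# Marker-table handling: domain assignment by marker proportion, per-marker
# alignment concatenation with mask trimming, and the genome-quality screen.
# Marker identification itself (gene calling + HMM search) is outside this
# package: we consume hit tables with pre-aligned rows.

#' Assign a genome to a domain by marker proportion
#'
#' The genome goes to the domain (Bacteria vs Archaea) with the strictly
#' higher proportion of identified marker genes; equal proportions are
#' `"ambiguous"`, no markers at all is `"undetermined"`.
#'
#' @param bac_hits,bac_total Bacterial markers found / in the set (the
#'   canonical bacterial set has 120 markers).
#' @param arc_hits,arc_total Archaeal markers found / in the set (canonical
#'   set: 122 markers).
#' @return List with `domain` (one of `"Bacteria"`, `"Archaea"`,
#'   `"ambiguous"`, `"undetermined"`) and `warnings`.
#' @export
assign_domain <- function(bac_hits, bac_total, arc_hits, arc_total) {
  if (bac_total <= 0 || arc_total <= 0) {
    tp_error("marker set totals must be positive", "taxoplace_validation_error")
  }
  if (bac_hits < 0 || arc_hits < 0 || bac_hits > bac_total ||
      arc_hits > arc_total) {
    tp_error("marker hit counts out of range", "taxoplace_validation_error")
  }
  pb <- bac_hits / bac_total
  pa <- arc_hits / arc_total
  if (pb == 0 && pa == 0) {
    return(list(domain = "undetermined",
                warnings = "no marker genes identified in either domain set"))
  }
  if (pb == pa) {
    return(list(domain = "ambiguous",
                warnings = sprintf(
                  "equal marker proportions (%.4f) for both domains", pb)))
  }
  list(domain = if (pb > pa) "Bacteria" else "Archaea", warnings = character())
}

#' Concatenate per-marker rows and apply the column mask
#'
#' Missing markers are filled with gaps of that marker's width before
#' masking, so every genome's row has exactly the mask's width after
#' trimming.
#'
#' @param rows Named list/vector of aligned rows (names = marker ids);
#'   markers absent from `rows` are gap-filled.
#' @param marker_order Character vector fixing the concatenation order.
#' @param marker_widths Named integer vector of per-marker alignment widths.
#' @param mask Logical vector over the concatenated columns (`TRUE` = keep);
#'   its length must equal `sum(marker_widths)`.
#' @param gap Gap character (default `-`).
#' @return Single string: the masked concatenated row.
#' @export
concat_and_mask <- function(rows, marker_order, marker_widths, mask,
                            gap = "-") {
  widths <- marker_widths[marker_order]
  if (anyNA(widths)) {
    tp_error("marker_order contains markers without declared widths",
             "taxoplace_validation_error")
  }
  if (length(mask) != sum(widths)) {
    tp_error(sprintf("mask length %d != total alignment width %d",
                     length(mask), sum(widths)),
             "taxoplace_validation_error")
  }
  pieces <- vapply(marker_order, function(m) {
    row <- if (m %in% names(rows)) rows[[m]] else NA_character_
    if (is.na(row) || !nzchar(row)) {
      strrep(gap, widths[[m]])
    } else {
      if (nchar(row) != widths[[m]]) {
        tp_error(sprintf("row for marker %s has width %d, expected %d",
                         m, nchar(row), widths[[m]]),
                 "taxoplace_validation_error")
      }
      row
    }
  }, character(1))
  cat_row <- paste(pieces, collapse = "")
  chars <- strsplit(cat_row, "", fixed = TRUE)[[1]]
  paste(chars[mask], collapse = "")
}

#' Genome quality screen
#'
#' Pass iff completeness >= `min_completeness` and contamination <=
#' `max_contamination` (both boundaries inclusive). The screen is advisory
#' by default: the pipeline warns on failures and only excludes them under
#' strict QC.
#'
#' @param completeness Completeness percentage in `[0, 100]`.
#' @param contamination Contamination percentage (>= 0).
#' @param min_completeness Threshold (default 50).
#' @param max_contamination Threshold (default 10).
#' @return List with `pass` (logical) and `warnings`.
#' @export
qc_filter <- function(completeness, contamination, min_completeness = 50,
                      max_contamination = 10) {
  if (is.na(completeness) || is.na(contamination) ||
      completeness < 0 || contamination < 0) {
    tp_error("completeness/contamination must be non-negative numbers",
             "taxoplace_validation_error")
  }
  pass <- completeness >= min_completeness &&
    contamination <= max_contamination
  warnings <- if (pass) character() else sprintf(
    "failed QC: completeness %.1f%% (min %.1f) / contamination %.1f%% (max %.1f)",
    completeness, min_completeness, contamination, max_contamination)
  list(pass = pass, warnings = warnings)
}
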