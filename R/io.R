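# Tabular and FASTA io: classification summary, species radii, column masks,
# marker hit tables, genome quality tables.

#' Create a classification result
#'
#' @param genome Query genome id.
#' @param taxonomy Character vector of length 7 (see [parse_taxonomy()]).
#' @param method One of `"ANI"`, `"TOPOLOGY"`, `"RED"`, or `""` for a query
#'   excluded before classification (strict QC).
#' @param closest_reference Reference genome id or `NA`.
#' @param ani_pct ANI percentage or `NA`.
#' @param align_frac Alignment fraction or `NA`.
#' @param red_value RED of the attachment point or `NA`.
#' @param warnings Character vector of warnings.
#' @return An object of class `classification_result`.
#' @export
classification_result <- function(genome, taxonomy, method,
                                  closest_reference = NA_character_,
                                  ani_pct = NA_real_, align_frac = NA_real_,
                                  red_value = NA_real_,
                                  warnings = character()) {
  validate_taxonomy(taxonomy)
  if (!method %in% c("ANI", "TOPOLOGY", "RED", "")) {
    tp_error("unknown classification method", "taxoplace_validation_error")
  }
  if (method == "ANI" && (!rank_filled(taxonomy)[7] || is.na(ani_pct))) {
    tp_error("method ANI requires a species and an ANI value",
             "taxoplace_validation_error")
  }
  if (method %in% c("TOPOLOGY", "RED") && rank_filled(taxonomy)[7]) {
    tp_error("topology/RED classifications cannot resolve species",
             "taxoplace_validation_error")
  }
  structure(list(genome = genome, taxonomy = taxonomy, method = method,
                 closest_reference = closest_reference, ani_pct = ani_pct,
                 align_frac = align_frac, red_value = red_value,
                 warnings = warnings),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s -> %s [%s]\n", x$genome, format_taxonomy(x$taxonomy),
              x$method))
  invisible(x)
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "fg", flag = "#"))
}

#' Write the classification summary TSV
#'
#' Columns (fixed order): `user_genome`, `classification`,
#' `closest_reference`, `ani`, `af`, `red_value`, `method`, `warnings`.
#'
#' @param results List of [classification_result()] objects.
#' @param path Output path.
#' @return Invisibly, the summary as a data.frame.
#' @export
write_summary <- function(results, path) {
  df <- summary_frame(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Build the summary data.frame without writing it
#'
#' @param results List of [classification_result()] objects.
#' @return data.frame with the eight summary columns.
#' @export
summary_frame <- function(results) {
  cols <- c("user_genome", "classification", "closest_reference", "ani",
            "af", "red_value", "method", "warnings")
  if (length(results) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols))
    return(df)
  }
  rows <- lapply(results, function(r) {
    data.frame(
      user_genome = r$genome,
      classification = format_taxonomy(r$taxonomy),
      closest_reference = ifelse(is.na(r$closest_reference), "",
                                 r$closest_reference),
      ani = fmt_num(r$ani_pct, 6),
      af = fmt_num(r$align_frac, 4),
      red_value = fmt_num(r$red_value, 6),
      method = r$method,
      warnings = paste(r$warnings, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read a species circumscription-radius table
#'
#' @param path TSV with columns `species_name`, `representative_genome`,
#'   `radius_pct`.
#' @return data.frame with those columns.
#' @export
read_radii <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_name", "representative_genome", "radius_pct")
  if (!all(need %in% names(df))) {
    tp_error("radii table must have species_name, representative_genome, radius_pct",
             "taxoplace_format_error")
  }
  bad <- !is.na(df$radius_pct) & (df$radius_pct <= 50 | df$radius_pct > 100)
  if (any(bad)) {
    tp_error("radius_pct must lie in (50, 100]", "taxoplace_validation_error")
  }
  df[need]
}

#' Write a species circumscription-radius table
#' @param radii data.frame as returned by [read_radii()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_radii <- function(radii, path) {
  utils::write.table(radii, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an alignment column mask
#'
#' @param path File whose first line is a string of `0`/`1` characters, one
#'   per concatenated alignment column.
#' @return Logical vector (`TRUE` = keep column).
#' @export
read_mask <- function(path) {
  line <- readLines(path, warn = FALSE)[1]
  bits <- strsplit(trimws(line), "", fixed = TRUE)[[1]]
  if (!all(bits %in% c("0", "1"))) {
    tp_error("mask must consist of 0/1 characters", "taxoplace_format_error")
  }
  bits == "1"
}

#' Write an alignment column mask
#' @param mask Logical vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_mask <- function(mask, path) {
  writeLines(paste(ifelse(mask, "1", "0"), collapse = ""), path)
  invisible(path)
}

#' Read a marker hit table
#'
#' @param path TSV with columns `genome`, `marker`, `present` (0/1 or
#'   TRUE/FALSE) and `aligned_row` (may be empty).
#' @return data.frame with those columns (`present` as logical).
#' @export
read_marker_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(aligned_row = "character"))
  need <- c("genome", "marker", "present", "aligned_row")
  if (!all(need %in% names(df))) {
    tp_error("marker hit table must have genome, marker, present, aligned_row",
             "taxoplace_format_error")
  }
  df$present <- if (is.character(df$present)) {
    df$present %in% c("1", "TRUE", "true")
  } else {
    as.logical(df$present)
  }
  df[need]
}

#' Write a marker hit table
#' @param hits data.frame as returned by [read_marker_hits()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_marker_hits <- function(hits, path) {
  hits$present <- as.integer(hits$present)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genome quality (completeness/contamination) table
#'
#' @param path TSV with columns `genome`, `completeness`, `contamination`
#'   (CheckM-style percentages).
#' @return data.frame with those columns.
#' @export
read_quality <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "completeness", "contamination")
  if (!all(need %in% names(df))) {
    tp_error("quality table must have genome, completeness, contamination",
             "taxoplace_format_error")
  }
  df[need]
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
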