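# Seven-rank, rank-prefixed taxonomy strings (d__;p__;c__;o__;f__;g__;s__).

#' Rank letters, prefixes and names
#'
#' The seven canonical ranks used throughout the package, in order from most
#' inclusive (domain) to least inclusive (species).
#'
#' @format Character vectors of length 7.
#' @name ranks
#' @keywords internal
NULL

TAX_RANKS <- c("d", "p", "c", "o", "f", "g", "s")
TAX_PREFIXES <- paste0(TAX_RANKS, "__")
TAX_RANK_NAMES <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Create an empty taxonomy
#'
#' @return Character vector of length 7 holding the bare rank prefixes
#'   (`"d__"`, `"p__"`, ...), i.e. a fully unresolved taxonomy.
#' @export
empty_taxonomy <- function() {
  stats::setNames(TAX_PREFIXES, TAX_RANKS)
}

#' Rank index of a prefixed taxon label
#'
#' @param label A rank-prefixed name such as `"p__Actinobacteriota"`.
#' @return Integer in 1..7, or `NA` if the label carries no known prefix.
#' @export
rank_of_label <- function(label) {
  pfx <- substr(label, 1L, 3L)
  idx <- match(pfx, TAX_PREFIXES)
  as.integer(idx)
}

#' Parse a semicolon-joined taxonomy string
#'
#' @param x String like `"d__Bacteria;p__Foo;c__;o__;f__;g__;s__"`. Missing
#'   trailing ranks are padded with empty prefixes; whitespace around
#'   separators is ignored.
#' @return Character vector of length 7, named by rank letter.
#' @export
parse_taxonomy <- function(x) {
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  tax <- empty_taxonomy()
  for (p in parts) {
    if (!nzchar(p)) next
    r <- rank_of_label(p)
    if (is.na(r)) {
      stop(errorCondition(sprintf("taxon label without rank prefix: '%s'", p),
                          class = c("taxoplace_validation_error", "error", "condition")))
    }
    tax[r] <- p
  }
  tax
}

#' Format a taxonomy as a semicolon-joined string
#'
#' @param tax Character vector of length 7 (see [parse_taxonomy()]).
#' @return Single string `"d__...;p__...;...;s__..."`.
#' @export
format_taxonomy <- function(tax) {
  paste(tax, collapse = ";")
}

#' Which ranks of a taxonomy are resolved
#'
#' @param tax Character vector of length 7 (see [parse_taxonomy()]).
#' @return Logical vector of length 7: `TRUE` where the rank holds an actual
#'   name beyond its bare prefix.
#' @export
rank_filled <- function(tax) {
  nchar(tax) > 3L
}

#' Check prefix closure of a taxonomy
#'
#' A taxonomy is prefix-closed when no resolved rank appears below an
#' unresolved one (resolution proceeds domain to species without gaps).
#'
#' @param tax Character vector of length 7.
#' @return Logical scalar.
#' @export
is_prefix_closed <- function(tax) {
  f <- rank_filled(tax)
  if (!any(f)) return(TRUE)
  last <- max(which(f))
  all(f[seq_len(last)])
}

#' Deepest resolved rank
#'
#' @param tax Character vector of length 7.
#' @return Integer rank index of the deepest non-empty rank, or 0 when fully
#'   unresolved.
#' @keywords internal
deepest_rank <- function(tax) {
  f <- which(rank_filled(tax))
  if (length(f) == 0L) 0L else max(f)
}

validate_taxonomy <- function(tax) {
  stopifnot(length(tax) == 7L)
  if (!all(substr(tax, 1L, 3L) == TAX_PREFIXES)) {
    stop(errorCondition("rank prefixes out of order or malformed",
                        class = c("taxoplace_validation_error", "error", "condition")))
  }
  if (!is_prefix_closed(tax)) {
    stop(errorCondition("taxonomy is not prefix-closed",
                        class = c("taxoplace_validation_error", "error", "condition")))
  }
  invisible(tax)
}
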