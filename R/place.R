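# Query attachment: a naive alignment-distance placer (fallback) and edge
# grafting. The naive placer attaches a query to the terminal edge of its
# nearest reference leaf under pairwise-deletion p-distance; likelihood
# placement (pplacer-style) is ingested via jplace instead.

#' Pairwise-deletion p-distance between two aligned rows
#'
#' Columns where either row holds a gap are ignored; the distance is the
#' fraction of mismatching remaining columns.
#'
#' @param a,b Aligned rows (equal-width strings).
#' @param gap Gap character (default `-`).
#' @return List with `dist` (p-distance, `NA` if no shared columns) and
#'   `n_sites` (columns compared).
#' @export
p_distance <- function(a, b, gap = "-") {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    tp_error("aligned rows differ in width", "taxoplace_validation_error")
  }
  g <- charToRaw(gap)
  ok <- ra != g & rb != g
  n <- sum(ok)
  if (n == 0L) return(list(dist = NA_real_, n_sites = 0L))
  list(dist = sum(ra[ok] != rb[ok]) / n, n_sites = n)
}

#' Place a query on the reference tree by alignment distance
#'
#' Finds the reference leaf minimizing the pairwise-deletion p-distance to
#' the query row and returns a placement at the leaf end of that leaf's
#' terminal edge, with the p-distance as the pendant length. Ties go to the
#' lexicographically smallest leaf id (with a warning on the placement).
#'
#' @param query Named list with `id` and `row` (masked concatenated
#'   alignment row), or a single named character string.
#' @param ref_alignment Named character vector: leaf genome id -> aligned
#'   row, all rows the same width as the query row.
#' @param tree A [ref_tree()] whose leaf genome ids include the alignment
#'   names.
#' @return A [placement()]; attribute-like fields `warnings` and
#'   `closest_leaf` record the decision.
#' @export
naive_place <- function(query, ref_alignment, tree) {
  if (is.character(query)) {
    query <- list(id = names(query)[1], row = unname(query[1]))
  }
  if (length(ref_alignment) < 2L) {
    tp_error("need at least two reference rows", "taxoplace_validation_error")
  }
  widths <- nchar(ref_alignment)
  if (length(unique(widths)) != 1L || nchar(query$row) != widths[1]) {
    tp_error("alignment rows differ in width", "taxoplace_validation_error")
  }
  warnings <- character()
  nongap <- sum(charToRaw(query$row) != charToRaw("-"))
  if (nongap == 0L) {
    tp_error("query row is entirely gaps", "taxoplace_validation_error")
  }
  if (nongap < 0.10 * nchar(query$row)) {
    warnings <- c(warnings, "low-quality query: <10% non-gap columns")
  }
  ids <- sort(names(ref_alignment))
  d <- vapply(ids, function(id) p_distance(query$row, ref_alignment[[id]])$dist,
              numeric(1))
  if (all(is.na(d))) {
    tp_error("query shares no aligned columns with any reference",
             "taxoplace_validation_error")
  }
  dmin <- min(d, na.rm = TRUE)
  hits <- ids[!is.na(d) & d == dmin]
  if (length(hits) > 1L) {
    warnings <- c(warnings, sprintf("placement tie among {%s}; kept %s",
                                    paste(hits, collapse = ", "), hits[1]))
  }
  best <- hits[1]   # ids sorted, so hits[1] is lexicographically smallest
  lf <- leaf_id(tree, best)
  if (is.na(lf)) {
    tp_error(sprintf("leaf '%s' absent from tree", best),
             "taxoplace_validation_error")
  }
  pl <- placement(edge = lf, distal_length = tree$edge_length[lf],
                  pendant_length = dmin)
  pl$warnings <- warnings
  pl$closest_leaf <- best
  pl
}

#' Graft a query onto the reference tree
#'
#' Splits the host edge at `distal_length` from its parent end, inserts a
#' new attachment node there and hangs the query leaf from it by the pendant
#' branch. Original node ids are preserved; the attachment node and the
#' query leaf get the next two ids.
#'
#' @param tree A [ref_tree()].
#' @param query_id Genome id for the new leaf (must not collide with an
#'   existing leaf).
#' @param placement A [placement()] on `tree`.
#' @return List with `tree` (the grafted [ref_tree()]), `attachment`
#'   (node id of the new internal node) and `query_leaf` (node id of the new
#'   leaf).
#' @export
graft <- function(tree, query_id, placement) {
  check_placement_on(tree, placement)
  if (query_id %in% tree$leaf_name) {
    tp_error(sprintf("query id '%s' collides with a reference leaf", query_id),
             "taxoplace_validation_error")
  }
  child <- placement$edge
  par <- tree$parent[child]
  len <- tree$edge_length[child]
  m <- tree$n + 1L   # attachment node
  q <- tree$n + 2L   # query leaf

  parent <- c(tree$parent, par, m)
  parent[child] <- m
  edge_length <- c(tree$edge_length, placement$distal_length,
                   placement$pendant_length)
  edge_length[child] <- max(0, len - placement$distal_length)
  leaf_name <- c(tree$leaf_name, NA_character_, query_id)
  support <- c(tree$support, NA_real_, NA_real_)
  taxa <- c(tree$taxa, list(character(), character()))
  name <- c(tree$name, NA_character_, NA_character_)
  edge_num <- c(tree$edge_num, NA_integer_, NA_integer_)

  gt <- ref_tree(parent = parent, edge_length = edge_length,
                 leaf_name = leaf_name, support = support, taxa = taxa,
                 name = name, edge_num = edge_num, validate = FALSE)
  list(tree = gt, attachment = m, query_leaf = q)
}
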