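# jplace v3 io. The embedded tree string carries {N} edge numbers; a
# placement's edge_num is resolved to the child node of that edge in the
# parsed tree.

#' Create a placement
#'
#' A query attachment point in jplace semantics: the edge (identified by its
#' child node), the distance along the edge from its parent end, and the
#' pendant branch length.
#'
#' @param edge Child-node id of the host edge.
#' @param distal_length Distance from the parent end of the edge, in
#'   `[0, edge length]`.
#' @param pendant_length Pendant branch length (>= 0).
#' @param like_weight_ratio Optional likelihood weight ratio in `[0, 1]`.
#' @param edge_num Optional jplace edge number.
#' @return An object of class `placement`.
#' @export
placement <- function(edge, distal_length, pendant_length,
                      like_weight_ratio = NA_real_, edge_num = NA_integer_) {
  if (distal_length < 0 || pendant_length < 0) {
    tp_error("placement lengths must be non-negative",
             "taxoplace_validation_error")
  }
  structure(list(edge = as.integer(edge),
                 distal_length = as.numeric(distal_length),
                 pendant_length = as.numeric(pendant_length),
                 like_weight_ratio = as.numeric(like_weight_ratio),
                 edge_num = as.integer(edge_num)),
            class = "placement")
}

check_placement_on <- function(tr, pl) {
  if (pl$edge < 1L || pl$edge > tr$n || pl$edge == tr$root) {
    tp_error("placement edge is not an edge of the tree",
             "taxoplace_validation_error")
  }
  len <- tr$edge_length[pl$edge]
  if (pl$distal_length > len + 1e-9) {
    tp_error("distal_length exceeds edge length", "taxoplace_validation_error")
  }
  invisible(pl)
}

#' Read a jplace placement file
#'
#' Parses the embedded `{N}`-numbered tree and resolves each placement's
#' `edge_num` against it. When a query has several placements the one with
#' the highest `like_weight_ratio` is kept (ties: lowest edge number, with a
#' warning recorded on the placement).
#'
#' @param path Path to a jplace JSON file.
#' @return List with elements `tree` (a [ref_tree()]) and `placements`
#'   (named list of [placement()] objects, one per query).
#' @export
read_jplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("tree", "placements", "fields")) {
    if (is.null(doc[[key]])) {
      tp_error(sprintf("jplace document missing '%s'", key),
               "taxoplace_format_error")
    }
  }
  fields <- unlist(doc$fields)
  for (f in c("edge_num", "distal_length", "pendant_length")) {
    if (!f %in% fields) {
      tp_error(sprintf("jplace fields missing '%s'", f),
               "taxoplace_format_error")
    }
  }
  tr <- read_newick(doc$tree)
  if (all(is.na(tr$edge_num))) {
    tp_error("jplace tree has no {N} edge numbers", "taxoplace_format_error")
  }
  edge_of <- rep(NA_integer_, max(tr$edge_num, na.rm = TRUE) + 1L)
  ok <- which(!is.na(tr$edge_num))
  edge_of[tr$edge_num[ok] + 1L] <- ok

  out <- list()
  for (p in doc$placements) {
    qname <- if (!is.null(p$n)) as.character(p$n[[1]])
             else if (!is.null(p$nm)) as.character(p$nm[[1]][[1]])
             else tp_error("placement without query name",
                           "taxoplace_format_error")
    rows <- lapply(p$p, function(row) {
      stats::setNames(as.list(row), fields)
    })
    pls <- lapply(rows, function(r) {
      en <- as.integer(r$edge_num)
      if (en + 1L > length(edge_of) || is.na(edge_of[en + 1L])) {
        tp_error(sprintf("edge_num %d not present in jplace tree", en),
                 "taxoplace_validation_error")
      }
      lwr <- if (!is.null(r$like_weight_ratio))
        as.numeric(r$like_weight_ratio) else NA_real_
      placement(edge = edge_of[en + 1L],
                distal_length = as.numeric(r$distal_length),
                pendant_length = as.numeric(r$pendant_length),
                like_weight_ratio = lwr, edge_num = en)
    })
    best <- pick_best_placement(pls)
    check_placement_on(tr, best)
    out[[qname]] <- best
  }
  list(tree = tr, placements = out)
}

pick_best_placement <- function(pls) {
  if (length(pls) == 1L) return(pls[[1]])
  lwr <- vapply(pls, function(p) {
    if (is.na(p$like_weight_ratio)) -Inf else p$like_weight_ratio
  }, numeric(1))
  top <- which(lwr == max(lwr))
  if (length(top) > 1L) {
    en <- vapply(pls[top], function(p) p$edge_num, integer(1))
    sel <- top[which.min(en)]
    best <- pls[[sel]]
    best$warnings <- "multiple placements with equal like_weight_ratio; kept lowest edge"
    best
  } else {
    pls[[top]]
  }
}

#' Write a jplace placement file
#'
#' @param tree A [ref_tree()]; `{N}` edge numbers are assigned as `node - 1`
#'   for every non-root node if absent.
#' @param placements Named list of [placement()] objects (names = query ids).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_jplace <- function(tree, placements, path) {
  if (all(is.na(tree$edge_num))) {
    tree$edge_num <- seq_len(tree$n) - 1L
    tree$edge_num[tree$root] <- NA_integer_
  }
  fields <- c("edge_num", "like_weight_ratio", "distal_length",
              "pendant_length")
  pl <- lapply(names(placements), function(q) {
    p <- placements[[q]]
    en <- tree$edge_num[p$edge]
    lwr <- if (is.na(p$like_weight_ratio)) 1.0 else p$like_weight_ratio
    list(p = list(list(en, lwr, p$distal_length, p$pendant_length)),
         n = list(q))
  })
  doc <- list(version = 3L,
              tree = write_newick(tree, edge_nums = TRUE),
              placements = pl,
              fields = as.list(fields),
              metadata = list(invocation = "taxoplace"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
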