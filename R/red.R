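# Relative evolutionary divergence (RED).
#
# RED normalizes taxonomic ranks across lineages with unequal rates of
# evolution: the root is pinned at 0, every leaf at 1, and an internal node n
# with parent p gets red(n) = red(p) + (d/u) * (1 - red(p)), where d is the
# branch length p->n and u is the mean branch-length path from p to the
# leaves descended from n (so u = d + mean depth below n, and d <= u always:
# RED is non-decreasing from root to leaves on any tree).

#' Compute RED for every node of a rooted tree
#'
#' @param tree A [ref_tree()] with all branch lengths present and at least
#'   two leaves.
#' @return Numeric vector (class `red_map`) of RED values indexed by node id;
#'   root = 0, leaves = 1.
#' @export
compute_red <- function(tree) {
  require_lengths(tree)
  leaves <- tree_leaves(tree)
  if (length(leaves) < 2L) {
    tp_error("RED requires a rooted tree with at least two leaves",
             "taxoplace_validation_error")
  }
  n <- tree$n
  nlv <- integer(n)     # leaves under node
  sdist <- numeric(n)   # sum of path lengths node -> descendant leaves
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) {
      nlv[v] <- 1L
      sdist[v] <- 0
    } else {
      nlv[v] <- sum(nlv[kids])
      sdist[v] <- sum(sdist[kids] + nlv[kids] * tree$edge_length[kids])
    }
  }
  red <- numeric(n)
  for (v in preorder(tree)) {
    if (v == tree$root) {
      red[v] <- 0
      next
    }
    if (length(tree$children[[v]]) == 0L) {
      red[v] <- 1
      next
    }
    p <- tree$parent[v]
    d <- tree$edge_length[v]
    u <- d + sdist[v] / nlv[v]
    red[v] <- if (u <= 0 || d <= 0) red[p] else
      red[p] + (d / u) * (1 - red[p])
  }
  structure(red, class = "red_map")
}

#' Median RED per taxonomic rank
#'
#' Medians are taken over labeled *internal* nodes only (species labels on
#' leaves are ANI territory, not RED), for the five intermediate ranks
#' phylum..genus. A rank with no labeled internal node is simply absent from
#' the result.
#'
#' @param tree A [ref_tree()].
#' @param redmap Result of [compute_red()].
#' @return Named numeric vector; names are rank letters among
#'   `c("p","c","o","f","g")`.
#' @export
rank_medians <- function(tree, redmap) {
  vals <- stats::setNames(vector("list", 5), c("p", "c", "o", "f", "g"))
  internal <- which(lengths(tree$children) > 0L)
  for (v in internal) {
    for (lab in tree$taxa[[v]]) {
      r <- TAX_RANKS[rank_of_label(lab)]
      if (r %in% names(vals)) vals[[r]] <- c(vals[[r]], redmap[v])
    }
  }
  keep <- lengths(vals) > 0L
  vapply(vals[keep], stats::median, numeric(1))
}

#' RED of a query attachment point
#'
#' Linear interpolation of RED along the host edge; the pendant branch does
#' not contribute (the query must be comparable to reference nodes whose RED
#' ignores it).
#'
#' @param tree A [ref_tree()].
#' @param redmap Result of [compute_red()].
#' @param placement A [placement()] on `tree`.
#' @return RED value in `[0, 1]`.
#' @export
red_at_placement <- function(tree, redmap, placement) {
  check_placement_on(tree, placement)
  child <- placement$edge
  par <- tree$parent[child]
  len <- tree$edge_length[child]
  if (len <= 0) return(unclass(redmap)[par])
  frac <- placement$distal_length / len
  unname(redmap[par] + frac * (redmap[child] - redmap[par]))
}

#' RED table for a tree
#'
#' @param tree A [ref_tree()].
#' @param redmap Result of [compute_red()].
#' @return data.frame with columns `node_id`, `red`, `taxa`.
#' @export
red_table <- function(tree, redmap) {
  data.frame(node_id = seq_len(tree$n),
             red = as.numeric(redmap),
             taxa = vapply(tree$taxa, paste, character(1), collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Write the RED table as TSV
#' @param tree A [ref_tree()].
#' @param redmap Result of [compute_red()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_red_table <- function(tree, redmap, path) {
  utils::write.table(red_table(tree, redmap), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
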