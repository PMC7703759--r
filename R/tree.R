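# The ref_tree container: a rooted tree with branch lengths, per-node
# support values and rank-prefixed taxon labels, and per-leaf genome ids.
# Nodes are indexed 1..n in parse/construction order; the root's parent is NA.

#' Construct a reference tree
#'
#' Low-level constructor for the rooted, decorated tree used as the
#' coordinate system for every classification decision. Most users obtain a
#' `ref_tree` from [read_newick()] or [gen_reference()].
#'
#' @param parent Integer vector; `parent[i]` is the parent node of node `i`,
#'   `NA` for the root.
#' @param edge_length Numeric vector; length of the edge above node `i`
#'   (substitutions/site). `NA` allowed for the root only.
#' @param leaf_name Character vector; genome id for leaves, `NA` for internal
#'   nodes.
#' @param support Numeric vector of node supports in `[0, 100]`, `NA` when
#'   absent.
#' @param taxa List of character vectors of rank-prefixed taxon labels per
#'   node (may be empty).
#' @param name Character vector of plain (non-taxon, non-support) node names,
#'   `NA` when absent.
#' @param edge_num Integer vector of jplace `{N}` edge numbers, `NA` when
#'   absent.
#' @param validate Run structural validation (default `TRUE`).
#' @return An object of class `ref_tree`.
#' @export
ref_tree <- function(parent, edge_length, leaf_name,
                     support = rep(NA_real_, length(parent)),
                     taxa = rep(list(character()), length(parent)),
                     name = rep(NA_character_, length(parent)),
                     edge_num = rep(NA_integer_, length(parent)),
                     validate = TRUE) {
  n <- length(parent)
  stopifnot(length(edge_length) == n, length(leaf_name) == n,
            length(support) == n, length(taxa) == n, length(name) == n,
            length(edge_num) == n)
  tr <- structure(list(
    parent = as.integer(parent),
    edge_length = as.numeric(edge_length),
    leaf_name = as.character(leaf_name),
    support = as.numeric(support),
    taxa = taxa,
    name = as.character(name),
    edge_num = as.integer(edge_num),
    n = n
  ), class = "ref_tree")
  tr$root <- which(is.na(tr$parent))
  tr$children <- tree_children(tr)
  if (validate) validate_ref_tree(tr)
  tr
}

tree_children <- function(tr) {
  ch <- vector("list", tr$n)
  for (i in seq_len(tr$n)) ch[[i]] <- integer()
  ord <- which(!is.na(tr$parent))
  for (i in ord) ch[[tr$parent[i]]] <- c(ch[[tr$parent[i]]], i)
  ch
}

tp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

validate_ref_tree <- function(tr) {
  if (length(tr$root) != 1L) {
    tp_error("tree must have exactly one root", "taxoplace_validation_error")
  }
  if (tr$n < 1L) tp_error("empty tree", "taxoplace_validation_error")
  is_leaf <- lengths(tr$children) == 0L
  ln <- tr$leaf_name[is_leaf]
  if (anyNA(ln) || any(!nzchar(ln))) {
    tp_error("every leaf must carry a genome id", "taxoplace_validation_error")
  }
  if (anyDuplicated(ln)) {
    tp_error(sprintf("duplicate leaf name: %s", ln[duplicated(ln)][1]),
             "taxoplace_validation_error")
  }
  bl <- tr$edge_length[-tr$root]
  if (any(!is.na(bl) & bl < 0)) {
    tp_error("negative branch length", "taxoplace_validation_error")
  }
  # parent links must be acyclic and reach the root
  depth_of_all(tr)
  # taxon labels along any root->leaf path must be rank-ordered
  check_rank_order(tr)
  invisible(tr)
}

depth_of_all <- function(tr) {
  # node depth in edges; errors on cycles / disconnected nodes
  d <- rep(NA_integer_, tr$n)
  d[tr$root] <- 0L
  for (i in preorder(tr)[-1L]) d[i] <- d[tr$parent[i]] + 1L
  if (anyNA(d)) tp_error("disconnected node in tree", "taxoplace_validation_error")
  d
}

check_rank_order <- function(tr) {
  rk <- rep(0L, tr$n)
  for (i in preorder(tr)) {
    own <- tr$taxa[[i]]
    lo <- if (i == tr$root) 0L else rk[tr$parent[i]]
    if (length(own)) {
      r <- vapply(own, rank_of_label, integer(1))
      if (anyNA(r)) {
        tp_error(sprintf("unprefixed taxon label '%s'", own[which(is.na(r))[1]]),
                 "taxoplace_validation_error")
      }
      if (min(r) <= lo && lo > 0L) {
        tp_error(sprintf("taxon label '%s' at or above an ancestor's rank",
                         own[which.min(r)]),
                 "taxoplace_validation_error")
      }
      rk[i] <- max(r)
    } else {
      rk[i] <- lo
    }
  }
  invisible(TRUE)
}

#' @export
print.ref_tree <- function(x, ...) {
  cat(sprintf("ref_tree: %d nodes, %d leaves, root = node %d\n",
              x$n, length(tree_leaves(x)), x$root))
  invisible(x)
}

#' Leaf node indices of a tree
#' @param tr A `ref_tree`.
#' @return Integer vector of leaf node ids.
#' @export
tree_leaves <- function(tr) {
  which(lengths(tr$children) == 0L)
}

#' Preorder (root first) node ordering
#' @param tr A `ref_tree`.
#' @return Integer vector of node ids, parents before children.
#' @export
preorder <- function(tr) {
  out <- integer(tr$n)
  stack <- tr$root
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    kids <- tr$children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  if (k != tr$n) tp_error("disconnected node in tree", "taxoplace_validation_error")
  out
}

#' Postorder (children first) node ordering
#' @param tr A `ref_tree`.
#' @return Integer vector of node ids, children before parents.
#' @export
postorder <- function(tr) {
  rev(preorder(tr))
}

#' Node ids of all nodes in the subtree rooted at `node` (node included)
#' @param tr A `ref_tree`.
#' @param node Node id.
#' @return Integer vector of node ids.
#' @keywords internal
subtree_nodes <- function(tr, node) {
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, tr$children[[v]])
  }
  out
}

#' Leaf genome ids under a node
#' @param tr A `ref_tree`.
#' @param node Node id.
#' @return Character vector of genome ids.
#' @export
leaves_under <- function(tr, node) {
  nd <- subtree_nodes(tr, node)
  tr$leaf_name[nd[lengths(tr$children)[nd] == 0L]]
}

#' Path of node ids from the root to a node (both included)
#' @param tr A `ref_tree`.
#' @param node Node id.
#' @return Integer vector of node ids, root first.
#' @export
root_path <- function(tr, node) {
  p <- node
  while (!is.na(tr$parent[p[1]])) p <- c(tr$parent[p[1]], p)
  p
}

#' Look up a leaf node id by genome id
#' @param tr A `ref_tree`.
#' @param genome Genome id.
#' @return Integer node id (or `NA` if absent).
#' @export
leaf_id <- function(tr, genome) {
  lv <- tree_leaves(tr)
  lv[match(genome, tr$leaf_name[lv])]
}

# require every non-root branch length to be present (RED is undefined
# without lengths)
require_lengths <- function(tr) {
  bl <- tr$edge_length[-tr$root]
  if (anyNA(bl)) {
    tp_error("tree has missing branch lengths", "taxoplace_validation_error")
  }
  invisible(tr)
}
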