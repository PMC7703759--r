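# Decorated Newick io.
#
# Dialect: internal node labels are either a bare number (support), a bare
# rank-prefixed name (taxon), or a single-quoted "support:taxon[; taxon...]"
# string (the GTDB convention). jplace-style {N} edge numbers are accepted
# after the branch length. Quoted labels may contain any character; embedded
# single quotes are doubled ('').

#' Read a decorated Newick tree
#'
#' @param path Path to a Newick file, or a literal Newick string (detected by
#'   the presence of `(` / `;`).
#' @return A [ref_tree()].
#' @export
#' @examples
#' tr <- read_newick("(A:1.0,B:2.0)root;")
read_newick <- function(path) {
  text <- if (grepl("[(;]", path)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  tr <- parse_newick_text(text)
  require_lengths_soft(tr)
  tr
}

# lengths are required on every non-root edge; error early so RED can't be
# silently undefined
require_lengths_soft <- function(tr) {
  if (tr$n > 1L) require_lengths(tr)
  invisible(tr)
}

parse_newick_text <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$chars <- chars
  st$nc <- length(chars)
  st$parent <- integer()
  st$edge_length <- numeric()
  st$leaf_name <- character()
  st$support <- numeric()
  st$taxa <- list()
  st$name <- character()
  st$edge_num <- integer()
  st$is_leaf <- logical()

  skip_ws(st)
  if (st$i > st$nc) {
    tp_error("empty Newick input", "taxoplace_parse_error")
  }
  root <- parse_clade(st)
  skip_ws(st)
  if (st$i > st$nc || st$chars[st$i] != ";") {
    tp_error("Newick string must end with ';'", "taxoplace_parse_error")
  }
  st$i <- st$i + 1L
  skip_ws(st)
  if (st$i <= st$nc) {
    tp_error("trailing characters after ';'", "taxoplace_parse_error")
  }
  tr <- ref_tree(parent = st$parent, edge_length = st$edge_length,
                 leaf_name = st$leaf_name, support = st$support,
                 taxa = st$taxa, name = st$name, edge_num = st$edge_num)
  tr
}

skip_ws <- function(st) {
  while (st$i <= st$nc && grepl("^[ \t\r\n]$", st$chars[st$i])) {
    st$i <- st$i + 1L
  }
}

peek <- function(st) {
  if (st$i > st$nc) "" else st$chars[st$i]
}

new_node <- function(st, leaf) {
  k <- length(st$parent) + 1L
  st$parent[k] <- NA_integer_
  st$edge_length[k] <- NA_real_
  st$leaf_name[k] <- NA_character_
  st$support[k] <- NA_real_
  st$taxa[[k]] <- character()
  st$name[k] <- NA_character_
  st$edge_num[k] <- NA_integer_
  st$is_leaf[k] <- leaf
  k
}

# clade := "(" clade ("," clade)* ")" suffix | label suffix
parse_clade <- function(st) {
  skip_ws(st)
  if (peek(st) == "(") {
    st$i <- st$i + 1L
    kids <- integer()
    repeat {
      kids <- c(kids, parse_clade(st))
      skip_ws(st)
      ch <- peek(st)
      if (ch == ",") {
        st$i <- st$i + 1L
      } else if (ch == ")") {
        st$i <- st$i + 1L
        break
      } else {
        tp_error("unbalanced parentheses in Newick string",
                 "taxoplace_parse_error")
      }
    }
    me <- new_node(st, leaf = FALSE)
    for (k in kids) st$parent[k] <- me
    parse_suffix(st, me, leaf = FALSE)
    me
  } else {
    me <- new_node(st, leaf = TRUE)
    parse_suffix(st, me, leaf = TRUE)
    if (is.na(st$leaf_name[me])) {
      tp_error("leaf without a name", "taxoplace_parse_error")
    }
    me
  }
}

# suffix := [label] [":" number] ["{" int "}"]
parse_suffix <- function(st, node, leaf) {
  skip_ws(st)
  ch <- peek(st)
  if (ch == "'") {
    lab <- parse_quoted(st)
    apply_label(st, node, lab, leaf)
  } else if (!ch %in% c(":", ",", ")", ";", "{", "(", "")) {
    lab <- parse_bare(st)
    if (nzchar(lab)) apply_label(st, node, lab, leaf)
  }
  skip_ws(st)
  if (peek(st) == ":") {
    st$i <- st$i + 1L
    st$edge_length[node] <- parse_number(st)
  }
  skip_ws(st)
  if (peek(st) == "{") {
    st$i <- st$i + 1L
    num <- parse_bare(st)
    if (peek(st) != "}") tp_error("unterminated {N} edge tag",
                                  "taxoplace_parse_error")
    st$i <- st$i + 1L
    st$edge_num[node] <- as.integer(num)
  }
  invisible(NULL)
}

parse_quoted <- function(st) {
  stopifnot(peek(st) == "'")
  st$i <- st$i + 1L
  out <- character()
  repeat {
    if (st$i > st$nc) tp_error("unterminated quoted label",
                               "taxoplace_parse_error")
    ch <- st$chars[st$i]
    if (ch == "'") {
      if (st$i + 1L <= st$nc && st$chars[st$i + 1L] == "'") {
        out <- c(out, "'")
        st$i <- st$i + 2L
      } else {
        st$i <- st$i + 1L
        break
      }
    } else {
      out <- c(out, ch)
      st$i <- st$i + 1L
    }
  }
  paste(out, collapse = "")
}

parse_bare <- function(st) {
  out <- character()
  while (st$i <= st$nc &&
         !st$chars[st$i] %in% c("(", ")", ",", ":", ";", "{", "}", "'",
                                " ", "\t", "\r", "\n")) {
    out <- c(out, st$chars[st$i])
    st$i <- st$i + 1L
  }
  paste(out, collapse = "")
}

parse_number <- function(st) {
  skip_ws(st)
  tok <- parse_bare(st)
  x <- suppressWarnings(as.numeric(tok))
  if (is.na(x)) tp_error(sprintf("invalid branch length '%s'", tok),
                         "taxoplace_parse_error")
  x
}

looks_numeric <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

is_taxon_label <- function(x) {
  grepl("^[dpcofgs]__", x)
}

# internal-label semantics: "support:taxa", bare number = support only,
# bare prefixed = taxon only, anything else = plain node name
apply_label <- function(st, node, lab, leaf) {
  if (leaf) {
    st$leaf_name[node] <- lab
    return(invisible(NULL))
  }
  if (looks_numeric(lab)) {
    st$support[node] <- as.numeric(lab)
  } else if (grepl(":", lab, fixed = TRUE)) {
    head <- sub(":.*$", "", lab)
    rest <- sub("^[^:]*:", "", lab)
    if (looks_numeric(head)) {
      st$support[node] <- as.numeric(head)
      st$taxa[[node]] <- split_taxa(rest)
    } else {
      st$name[node] <- lab
    }
  } else if (is_taxon_label(lab)) {
    st$taxa[[node]] <- split_taxa(lab)
  } else {
    st$name[node] <- lab
  }
  invisible(NULL)
}

split_taxa <- function(x) {
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Write a decorated Newick tree
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(tr))` reconstructs
#' the tree with identical topology, branch lengths (10 significant digits),
#' supports and labels.
#'
#' @param tree A [ref_tree()].
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param edge_nums Emit `{N}` edge tags (default: only when present on the
#'   tree).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, edge_nums = NULL) {
  if (is.null(tree) || !inherits(tree, "ref_tree") || tree$n == 0L) {
    tp_error("cannot write an empty tree", "taxoplace_validation_error")
  }
  if (is.null(edge_nums)) edge_nums <- any(!is.na(tree$edge_num))
  txt <- paste0(newick_clade(tree, tree$root, edge_nums), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

newick_clade <- function(tr, node, edge_nums) {
  kids <- tr$children[[node]]
  body <- if (length(kids)) {
    paste0("(", paste(vapply(kids, function(k)
      newick_clade(tr, k, edge_nums), character(1)), collapse = ","), ")")
  } else ""
  lab <- node_label(tr, node)
  len <- tr$edge_length[node]
  suf <- if (!is.na(len)) paste0(":", sprintf("%.15g", len)) else ""
  tag <- if (edge_nums && !is.na(tr$edge_num[node]))
    paste0("{", tr$edge_num[node], "}") else ""
  paste0(body, lab, suf, tag)
}

needs_quotes <- function(x) {
  grepl("[(),:;'{} \t]", x)
}

quote_label <- function(x) {
  if (needs_quotes(x)) paste0("'", gsub("'", "''", x, fixed = TRUE), "'") else x
}

node_label <- function(tr, node) {
  if (lengths(tr$children)[node] == 0L) {
    return(quote_label(tr$leaf_name[node]))
  }
  sup <- tr$support[node]
  tx <- tr$taxa[[node]]
  nm <- tr$name[node]
  if (!is.na(nm)) return(quote_label(nm))
  if (length(tx) && !is.na(sup)) {
    quote_label(paste0(sprintf("%.10g", sup), ":", paste(tx, collapse = "; ")))
  } else if (length(tx)) {
    quote_label(paste(tx, collapse = "; "))
  } else if (!is.na(sup)) {
    sprintf("%.10g", sup)
  } else ""
}
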