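# The decision engine: combine ancestral taxonomy, topology constraints,
# RED and ANI into one classification per query.
#
# After grafting the query, the labels above the attachment fix the upper
# ranks; the labels below it bound the lower ranks. The ranks in between form
# the candidate window: the query's novel rank is one of them. A window of
# size one is decided by topology alone; larger windows are resolved by
# comparing the query's RED with per-rank median RED values. Species are
# never decided by RED: they are assigned (or refused) by ANI against the
# representative genomes of the candidate genus.

#' Taxonomy above an attachment point
#'
#' Union of the taxon labels on the path from the root to the attachment
#' node, as a prefix-closed partial taxonomy.
#'
#' @param tree A (typically grafted) [ref_tree()].
#' @param node Node id of the attachment (or any node).
#' @return Character vector of length 7 (see [parse_taxonomy()]).
#' @export
ancestor_taxonomy <- function(tree, node) {
  tax <- empty_taxonomy()
  for (v in root_path(tree, node)) {
    if (lengths(tree$children)[v] == 0L && v != node) next
    for (lab in tree$taxa[[v]]) {
      r <- rank_of_label(lab)
      if (rank_filled(tax)[r] && tax[r] != lab) {
        tp_error(sprintf("conflicting labels at rank %s on one path: %s vs %s",
                         TAX_RANK_NAMES[r], tax[r], lab),
                 "taxoplace_internal_error")
      }
      tax[r] <- lab
    }
  }
  tax
}

# labeled crown nodes of the subtree at `node`: labeled nodes with no
# labeled ancestor inside the subtree (descent stops at the first label)
crown_labeled_nodes <- function(tree, node) {
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (length(tree$taxa[[v]]) > 0L) {
      out <- c(out, v)
    } else {
      stack <- c(stack, tree$children[[v]])
    }
  }
  out
}

#' Candidate rank window for a grafted query
#'
#' The contiguous ranks the query's novel rank can take: strictly below the
#' deepest rank labeled above the attachment, and bounded below by the
#' labels in the attachment's descendant clades. When the descendant side is
#' a single taxon stack (one crown labeled node), the query may also split
#' that stack, so the window extends one rank past the stack's deepest rank;
#' when several distinct taxa sit below, the query can belong to none of
#' them and the window stops at their rank.
#'
#' @param tree Grafted [ref_tree()].
#' @param attachment Node id of the attachment node.
#' @param query_leaf Node id of the query leaf.
#' @return List with `window` (integer rank indices, most inclusive first),
#'   `ancestors` (partial taxonomy above), `crown_taxa` (partial taxonomy
#'   from the single crown stack, all-empty otherwise).
#' @export
candidate_ranks <- function(tree, attachment, query_leaf) {
  anc <- ancestor_taxonomy(tree, attachment)
  a <- deepest_rank(anc)
  if (a >= 7L) {
    # placed inside a species clade (e.g. on a genome's terminal edge):
    # species membership is ANI's call, which has already been refused by
    # the time we get here, so the query is at worst a novel species
    anc[7] <- TAX_PREFIXES[7]
    a <- 6L
  }
  kids <- setdiff(tree$children[[attachment]], query_leaf)
  crowns <- integer()
  for (k in kids) crowns <- c(crowns, crown_labeled_nodes(tree, k))

  crown_tax <- empty_taxonomy()
  if (length(crowns) == 0L) {
    upper <- 7L
  } else {
    ranks_per_crown <- lapply(crowns, function(v)
      vapply(tree$taxa[[v]], rank_of_label, integer(1)))
    s <- min(unlist(ranks_per_crown))
    if (length(crowns) == 1L) {
      t <- max(ranks_per_crown[[1]])
      upper <- min(t + 1L, 7L)
      for (lab in tree$taxa[[crowns[1]]]) {
        crown_tax[rank_of_label(lab)] <- lab
      }
    } else {
      upper <- s
    }
  }
  if (a + 1L > upper) {
    tp_error("empty candidate rank window (malformed labels around attachment)",
             "taxoplace_internal_error")
  }
  list(window = seq.int(a + 1L, upper), ancestors = anc,
       crown_taxa = crown_tax)
}

#' Resolve an ambiguous rank window by RED
#'
#' Picks the window rank whose median RED is nearest the query's RED. Ties
#' go to the more inclusive rank (conservative: under- rather than
#' over-classify). A window rank without a median (always the case for
#' species, possible for sparsely labeled references) forces a fallback to
#' the most inclusive window rank.
#'
#' @param window Integer rank indices (size >= 2).
#' @param medians Named numeric vector from [rank_medians()].
#' @param query_red RED of the attachment point.
#' @return List with `rank` (integer index of the chosen novel rank) and
#'   `warnings`.
#' @export
resolve_by_red <- function(window, medians, query_red) {
  stopifnot(length(window) >= 2L)
  letters <- TAX_RANKS[window]
  m <- medians[letters]
  if (anyNA(m)) {
    missing <- TAX_RANK_NAMES[window[is.na(m)]]
    return(list(rank = min(window), warnings = sprintf(
      "no RED median for rank(s) %s; falling back to most inclusive candidate rank (%s)",
      paste(missing, collapse = ", "), TAX_RANK_NAMES[min(window)])))
  }
  diffs <- abs(query_red - m)
  hits <- window[diffs <= min(diffs) + 1e-12]
  if (length(hits) > 1L) {
    list(rank = min(hits),
         warnings = "RED tie between candidate ranks; kept the more inclusive rank")
  } else {
    list(rank = hits[1], warnings = character())
  }
}

# taxonomy of a reference leaf (path labels incl. the leaf's own labels)
leaf_taxonomy <- function(tree, genome) {
  lf <- leaf_id(tree, genome)
  if (is.na(lf)) {
    tp_error(sprintf("genome '%s' not in tree", genome),
             "taxoplace_validation_error")
  }
  tax <- empty_taxonomy()
  for (v in root_path(tree, lf)) {
    for (lab in tree$taxa[[v]]) tax[rank_of_label(lab)] <- lab
  }
  tax
}

#' Candidate genus for ANI comparisons
#'
#' ANI is attempted whenever the attachment lies within, or immediately
#' adjacent to, a single genus clade: the ancestor genus if the attachment
#' is inside one, else the genus of a single crown stack directly below.
#'
#' @param tree Grafted [ref_tree()].
#' @param attachment Attachment node id.
#' @param query_leaf Query leaf node id.
#' @return Genus label (`"g__..."`) or `NA` when ANI does not apply.
#' @export
candidate_genus <- function(tree, attachment, query_leaf) {
  cand <- candidate_ranks(tree, attachment, query_leaf)
  if (rank_filled(cand$ancestors)[6]) return(unname(cand$ancestors[6]))
  if (rank_filled(cand$crown_taxa)[6]) return(unname(cand$crown_taxa[6]))
  NA_character_
}

#' Classify one query genome
#'
#' The full decision rule: (1) if the ANI species rule succeeds the query
#' gets the closest reference's species (method `ANI`); (2) otherwise the
#' grafted topology fixes the upper ranks and bounds the candidate window —
#' a window of one rank is decided by topology alone (method `TOPOLOGY`);
#' (3) larger windows are resolved by nearest median RED (method `RED`).
#' The chosen novel rank r* and everything below it stay empty, and a
#' `"novel <rank>"` warning is recorded.
#'
#' @param tree Reference [ref_tree()] (ungrafted).
#' @param redmap [compute_red()] of `tree`.
#' @param medians [rank_medians()] of `tree`.
#' @param placement A [placement()] of the query on `tree`.
#' @param ani_results List of `ani_result` objects against the candidate
#'   genus' representatives (may be empty).
#' @param radii Radii table (see [read_radii()]).
#' @param query_id Query genome id.
#' @param af_threshold Alignment-fraction threshold (default 0.65, strict).
#' @param default_radius Default circumscription radius (default 95).
#' @return A [classification_result()].
#' @export
classify_query <- function(tree, redmap, medians, placement, ani_results,
                           radii, query_id, af_threshold = 0.65,
                           default_radius = 95) {
  warnings <- character()
  qred <- red_at_placement(tree, redmap, placement)

  sp <- species_assign(ani_results, radii, af_threshold = af_threshold,
                       default_radius = default_radius)
  warnings <- c(warnings, sp$warnings)
  if (!is.na(sp$species)) {
    tax <- leaf_taxonomy(tree, sp$reference)
    tax[7] <- if (is_taxon_label(sp$species)) sp$species else
      paste0("s__", sp$species)
    return(classification_result(
      genome = query_id, taxonomy = tax, method = "ANI",
      closest_reference = sp$reference, ani_pct = sp$ani_pct,
      align_frac = sp$align_frac, red_value = qred, warnings = warnings))
  }

  g <- graft(tree, query_id, placement)
  cand <- candidate_ranks(g$tree, g$attachment, g$query_leaf)
  if (length(cand$window) == 1L) {
    rstar <- cand$window
    method <- "TOPOLOGY"
  } else {
    res <- resolve_by_red(cand$window, medians, qred)
    rstar <- res$rank
    method <- "RED"
    warnings <- c(warnings, res$warnings)
  }

  tax <- cand$ancestors
  a <- deepest_rank(tax)
  if (rstar - 1L > a) {
    # ranks between the ancestors and the novel rank come from the single
    # crown stack below the attachment (e.g. a basal order inside the sole
    # class of a phylum inherits that phylum and class)
    for (r in seq.int(a + 1L, rstar - 1L)) {
      if (rank_filled(cand$crown_taxa)[r]) {
        tax[r] <- cand$crown_taxa[r]
      } else {
        warnings <- c(warnings, sprintf(
          "no reference name available at rank %s; classification truncated",
          TAX_RANK_NAMES[r]))
        break
      }
    }
  }
  warnings <- c(warnings, sprintf("novel %s", TAX_RANK_NAMES[rstar]))

  best_ref <- NA_character_
  ani <- NA_real_
  af <- NA_real_
  if (length(ani_results) > 0L) {
    anis <- vapply(ani_results, function(r)
      ifelse(is.na(r$ani_pct), -Inf, r$ani_pct), numeric(1))
    b <- ani_results[[which.max(anis)]]
    if (is.finite(anis[which.max(anis)])) {
      best_ref <- b$reference
      ani <- b$ani_pct
      af <- b$align_frac
    }
  }
  classification_result(
    genome = query_id, taxonomy = tax, method = method,
    closest_reference = best_ref, ani_pct = ani, align_frac = af,
    red_value = qred, warnings = warnings)
}
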