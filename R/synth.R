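# Synthetic fixture generator: internally consistent reference packages
# (decorated tree + marker alignments + genomes + radii + mask) and query
# genomes with known truth, so the whole pipeline is testable offline.
#
# The reference tree is rank-stratified and ultrametric with fixed per-rank
# depths; on an ultrametric tree RED equals relative depth exactly, so the
# per-rank RED medians are known in closed form and well separated. Marker
# (amino acid) and genome (nucleotide) sequences evolve along the tree under
# uniform i.i.d. substitution, which makes identity expectations analytic:
# a direct mutation at rate d yields expected sequence identity 1 - d.

NT_ALPHA <- c("A", "C", "G", "T")
AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# per-rank crown depths (root = 0, leaves = 1); "join" nodes group phyla
# pairwise below the root when there are >= 4 of them
RANK_DEPTHS <- c(join = 0.15, p = 0.30, c = 0.45, o = 0.60, f = 0.72,
                 g = 0.85, s = 0.98, leaf = 1.00)

#' Specification of a synthetic reference package
#'
#' @param seed Master random seed (mandatory; every fixture is reproducible
#'   and all randomness flows from this seed through named substreams, one
#'   per sequence, so adding a genome never perturbs others).
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus
#'   Taxon counts per rank (all >= 1; a count of 1 stacks that rank's label
#'   onto its parent's crown node, as in real taxonomies).
#' @param genomes_per_species Genomes per species (default 1; the first is
#'   the species representative).
#' @param n_markers Number of marker genes (default 10).
#' @param marker_width Alignment width of each marker in columns
#'   (default 48).
#' @param mask_keep_frac Fraction of concatenated columns kept by the mask
#'   (default 0.85).
#' @param genome_length Genome length in bases (default 50000).
#' @param nt_rate Genome substitutions per unit branch length (default
#'   0.25: congeneric species then sit at ~92-93% ANI, safely outside a 95%
#'   radius, while conspecific genomes stay within it).
#' @param radius_pct Species ANI circumscription radius written to the radii
#'   table (default 95).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_phyla = 4L, classes_per_phylum = 2L,
                         orders_per_class = 2L, families_per_order = 2L,
                         genera_per_family = 2L, species_per_genus = 2L,
                         genomes_per_species = 1L,
                         n_markers = 10L, marker_width = 48L,
                         mask_keep_frac = 0.85,
                         genome_length = 50000L, nt_rate = 0.25,
                         radius_pct = 95) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    tp_error("fixture_spec requires a seed", "taxoplace_validation_error")
  }
  counts <- c(n_phyla, classes_per_phylum, orders_per_class,
              families_per_order, genera_per_family, species_per_genus,
              genomes_per_species)
  if (any(counts < 1L)) {
    tp_error("all per-rank counts must be >= 1", "taxoplace_validation_error")
  }
  if (prod(counts) < 2L) {
    tp_error("fixture must have at least 2 genomes",
             "taxoplace_validation_error")
  }
  structure(list(seed = as.integer(seed), n_phyla = n_phyla,
                 classes_per_phylum = classes_per_phylum,
                 orders_per_class = orders_per_class,
                 families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 genomes_per_species = genomes_per_species,
                 n_markers = n_markers, marker_width = marker_width,
                 mask_keep_frac = mask_keep_frac,
                 genome_length = genome_length, nt_rate = nt_rate,
                 radius_pct = radius_pct),
            class = "fixture_spec")
}

# deterministic substream: seed the RNG from (master seed, stream name)
substream_seed <- function(seed, name) {
  s0 <- as.numeric(seed) %% 2147483647
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + s0 * 7919) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

random_seq_int <- function(len, n_states) {
  sample.int(n_states, len, replace = TRUE)
}

# i.i.d. substitution: each site mutates with probability p to one of the
# other n_states - 1 states, uniformly
mutate_int <- function(seq, p, n_states) {
  L <- length(seq)
  p <- min(p, 0.95)
  n <- stats::rbinom(1L, L, p)
  if (n == 0L) return(seq)
  pos <- sample.int(L, n)
  shift <- sample.int(n_states - 1L, n, replace = TRUE)
  seq[pos] <- ((seq[pos] - 1L + shift) %% n_states) + 1L
  seq
}

int_to_seq <- function(x, alphabet) {
  paste(alphabet[x], collapse = "")
}

seq_to_int <- function(s, alphabet) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], alphabet)
}

#' Generate a synthetic reference package
#'
#' Builds the rank-stratified decorated tree, evolves marker alignments and
#' genomes along it, draws the column mask and writes per-species radii.
#' The same spec (same seed) always yields byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `synth_reference` with elements `tree`, `spec`,
#'   `node_genome` (per-node genome strings), `node_markers` (per-node named
#'   vectors of unmasked marker rows), `marker_order`, `marker_widths`,
#'   `mask`, `ref_alignment` (masked rows per leaf genome), `genomes` (leaf
#'   genome sequences), `radii`, `rank_depths`, `node_depth`.
#' @export
gen_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  counts <- c(p = spec$n_phyla, c = spec$classes_per_phylum,
              o = spec$orders_per_class, f = spec$families_per_order,
              g = spec$genera_per_family, s = spec$species_per_genus)

  st <- new.env(parent = emptyenv())
  st$parent <- integer(); st$edge_length <- numeric()
  st$leaf_name <- character(); st$taxa <- list()
  st$depth <- numeric(); st$stream <- character()
  add_node <- function(parent, depth, taxa = character(),
                       leaf_name = NA_character_, stream) {
    k <- length(st$parent) + 1L
    st$parent[k] <- parent
    st$depth[k] <- depth
    st$edge_length[k] <- if (is.na(parent)) NA_real_ else
      depth - st$depth[parent]
    st$taxa[[k]] <- taxa
    st$leaf_name[k] <- leaf_name
    st$stream[k] <- stream
    k
  }

  rank_letters <- c("p", "c", "o", "f", "g", "s")
  # crown node for the taxon at rank index r (1 = phylum) named `name`;
  # single-child ranks stack their label onto the same node
  make_taxon <- function(parent, r, name) {
    labels <- paste0(rank_letters[r], "__", name)
    rr <- r
    nm <- name
    while (rr < 6L && counts[rr + 1L] == 1L) {
      rr <- rr + 1L
      nm <- paste0(nm, toupper(rank_letters[rr]), 1L)
      labels <- c(labels, paste0(rank_letters[rr], "__", nm))
    }
    node <- add_node(parent, RANK_DEPTHS[[rank_letters[rr]]], labels,
                     stream = nm)
    if (rr == 6L) {
      for (i in seq_len(spec$genomes_per_species)) {
        gid <- sprintf("G_%s_%d", nm, i)
        add_node(node, RANK_DEPTHS[["leaf"]], leaf_name = gid, stream = gid)
      }
    } else {
      for (i in seq_len(counts[rr + 1L])) {
        make_taxon(node, rr + 1L,
                   paste0(nm, toupper(rank_letters[rr + 1L]), i))
      }
    }
    node
  }

  root <- add_node(NA_integer_, 0, taxa = "d__D1", stream = "root")
  if (spec$n_phyla >= 4L && spec$n_phyla %% 2L == 0L) {
    for (j in seq_len(spec$n_phyla / 2L)) {
      join <- add_node(root, RANK_DEPTHS[["join"]],
                       stream = sprintf("J%d", j))
      make_taxon(join, 1L, sprintf("P%d", 2L * j - 1L))
      make_taxon(join, 1L, sprintf("P%d", 2L * j))
    }
  } else {
    for (i in seq_len(spec$n_phyla)) make_taxon(root, 1L, sprintf("P%d", i))
  }

  tree <- ref_tree(parent = st$parent, edge_length = st$edge_length,
                   leaf_name = st$leaf_name, taxa = st$taxa)

  # sequences: evolve along the tree in preorder, one substream per node
  marker_order <- sprintf("M%02d", seq_len(spec$n_markers))
  marker_widths <- stats::setNames(rep(spec$marker_width, spec$n_markers),
                                   marker_order)
  node_genome_int <- vector("list", tree$n)
  node_marker_int <- vector("list", tree$n)
  for (v in preorder(tree)) {
    nm <- st$stream[v]
    if (v == tree$root) {
      node_genome_int[[v]] <- with_substream(spec$seed, "genome/root",
        random_seq_int(spec$genome_length, 4L))
      node_marker_int[[v]] <- with_substream(spec$seed, "markers/root",
        lapply(marker_order, function(m)
          random_seq_int(spec$marker_width, 20L)))
    } else {
      bl <- tree$edge_length[v]
      par <- tree$parent[v]
      node_genome_int[[v]] <- with_substream(
        spec$seed, paste0("genome/", nm),
        mutate_int(node_genome_int[[par]], bl * spec$nt_rate, 4L))
      node_marker_int[[v]] <- with_substream(
        spec$seed, paste0("markers/", nm),
        lapply(node_marker_int[[par]], mutate_int, p = bl, n_states = 20L))
    }
  }
  node_genome <- vapply(node_genome_int, int_to_seq, character(1),
                        alphabet = NT_ALPHA)
  node_markers <- lapply(node_marker_int, function(rows)
    stats::setNames(vapply(rows, int_to_seq, character(1),
                           alphabet = AA_ALPHA), marker_order))

  mask <- with_substream(spec$seed, "mask",
    stats::runif(sum(marker_widths)) < spec$mask_keep_frac)

  leaves <- tree_leaves(tree)
  leaf_ids <- tree$leaf_name[leaves]
  ref_alignment <- stats::setNames(vapply(leaves, function(v)
    concat_and_mask(node_markers[[v]], marker_order, marker_widths, mask),
    character(1)), leaf_ids)
  genomes <- stats::setNames(node_genome[leaves], leaf_ids)

  # one representative (the first genome) per species
  sp_nodes <- which(vapply(tree$taxa, function(tx)
    any(grepl("^s__", tx)), logical(1)))
  radii <- do.call(rbind, lapply(sp_nodes, function(v) {
    sname <- grep("^s__", tree$taxa[[v]], value = TRUE)[1]
    data.frame(species_name = sname,
               representative_genome = leaves_under(tree, v)[1],
               radius_pct = spec$radius_pct, stringsAsFactors = FALSE)
  }))
  radii <- radii[order(radii$species_name), , drop = FALSE]
  rownames(radii) <- NULL

  structure(list(tree = tree, spec = spec, node_genome = node_genome,
                 node_markers = node_markers, marker_order = marker_order,
                 marker_widths = marker_widths, mask = mask,
                 ref_alignment = ref_alignment, genomes = genomes,
                 radii = radii, rank_depths = RANK_DEPTHS,
                 node_depth = st$depth, node_stream = st$stream),
            class = "synth_reference")
}

#' @export
print.synth_reference <- function(x, ...) {
  cat(sprintf("synth_reference: %d leaves, %d species, %d markers, %d bp genomes (seed %d)\n",
              length(x$genomes), nrow(x$radii), length(x$marker_order),
              x$spec$genome_length, x$spec$seed))
  invisible(x)
}

# internal node whose taxa contain a given label
node_with_label <- function(tree, label) {
  for (v in seq_len(tree$n)) if (label %in% tree$taxa[[v]]) return(v)
  NA_integer_
}

QUERY_MODES <- c("known_species", "novel_species", "novel_genus",
                 "novel_phylum", "basal_ambiguous")

#' Generate a query genome with known truth
#'
#' Modes mirror the canonical placement scenarios: `known_species` mutates a
#' species representative below its circumscription radius;
#' `novel_species` mutates it beyond the radius but within the genus;
#' `novel_genus` evolves a genome from a family crown and attaches it basal
#' to a genus; `novel_phylum` attaches basal to several phyla;
#' `basal_ambiguous` attaches part-way along an inter-rank edge so that the
#' RED rule must decide (the truth rank is the nearest-median rank, computed
#' arithmetically from the generator's own depth table).
#'
#' @param reference A [gen_reference()] result.
#' @param mode One of `"known_species"`, `"novel_species"`,
#'   `"novel_genus"`, `"novel_phylum"`, `"basal_ambiguous"`.
#' @param seed Seed for this query's substreams.
#' @param id Query genome id (default derived from mode and seed).
#' @return List of class `synth_query` with `id`, `genome`, `marker_rows`
#'   (unmasked per-marker rows, some possibly missing), `placement` (the
#'   engineered [placement()] on the reference tree) and `truth` (a
#'   `TruthRecord`: `taxonomy`, `novel_rank`, `expected_closest`,
#'   `divergence`).
#' @export
gen_query <- function(reference, mode, seed, id = NULL) {
  ref <- reference
  if (!mode %in% QUERY_MODES) {
    tp_error(sprintf("unknown query mode '%s'", mode),
             "taxoplace_validation_error")
  }
  if (is.null(id)) id <- sprintf("Q_%s_%d", mode, seed)
  tree <- ref$tree
  seed2 <- substream_seed(seed, paste0("query/", mode))

  pick <- function(n, what) with_substream(seed2, paste0("pick/", what),
                                           sample.int(n, 1L))
  u01 <- function(what) with_substream(seed2, paste0("unif/", what),
                                       stats::runif(1L, 0.1, 0.9))

  sp_row <- ref$radii[pick(nrow(ref$radii), "species"), ]
  rep_leaf <- leaf_id(tree, sp_row$representative_genome)
  sp_node <- tree$parent[rep_leaf]          # species crown node
  rep_tax <- leaf_taxonomy(tree, sp_row$representative_genome)
  rep_tax[7] <- sp_row$species_name

  mutate_from <- function(node, d_genome, d_marker) {
    gseq <- seq_to_int(ref$node_genome[node], NT_ALPHA)
    genome <- int_to_seq(with_substream(seed2, "genome",
      mutate_int(gseq, d_genome, 4L)), NT_ALPHA)
    rows <- vapply(ref$marker_order, function(m) {
      int_to_seq(with_substream(seed2, paste0("marker/", m),
        mutate_int(seq_to_int(ref$node_markers[[node]][[m]], AA_ALPHA),
                   d_marker, 20L)), AA_ALPHA)
    }, character(1))
    drop <- with_substream(seed2, "dropout",
                           stats::runif(length(rows)) < 0.1)
    if (all(drop)) drop[1] <- FALSE
    list(genome = genome, rows = rows[!drop])
  }

  truth_tax <- empty_taxonomy()
  if (mode %in% c("known_species", "novel_species")) {
    d <- if (mode == "known_species") 0.02 else 0.08
    mq <- mutate_from(rep_leaf, d, d)
    pl <- placement(edge = sp_node,
                    distal_length = tree$edge_length[sp_node],
                    pendant_length = d)
    truth_tax <- rep_tax
    novel <- NA_character_
    if (mode == "novel_species") {
      truth_tax[7] <- "s__"
      novel <- "species"
    }
    truth <- list(taxonomy = truth_tax, novel_rank = novel,
                  expected_closest = sp_row$representative_genome,
                  divergence = d)
  } else if (mode == "novel_genus") {
    genus_lab <- rep_tax[6]
    genus_node <- node_with_label(tree, genus_lab)
    fam_node <- tree$parent[genus_node]
    d <- 0.04
    mq <- mutate_from(fam_node, d, 0.05)
    pl <- placement(edge = genus_node,
                    distal_length = u01("distal") * tree$edge_length[genus_node],
                    pendant_length = 0.05)
    truth_tax <- rep_tax
    truth_tax[6:7] <- TAX_PREFIXES[6:7]
    truth <- list(taxonomy = truth_tax, novel_rank = "genus",
                  expected_closest = NA_character_, divergence = d)
  } else if (mode == "novel_phylum") {
    kids <- tree$children[[tree$root]]
    joins <- kids[lengths(tree$taxa[kids]) == 0L]
    d <- 0.05
    if (length(joins) > 0L) {
      jn <- joins[pick(length(joins), "join")]
      mq <- mutate_from(jn, d, d)
      pl <- placement(edge = jn,
                      distal_length = u01("distal") * tree$edge_length[jn],
                      pendant_length = 0.05)
    } else {
      ph <- kids[pick(length(kids), "phylum")]
      mq <- mutate_from(ph, d, d)
      pl <- placement(edge = ph, distal_length = 0, pendant_length = 0.05)
    }
    truth_tax[1] <- "d__D1"
    truth <- list(taxonomy = truth_tax, novel_rank = "phylum",
                  expected_closest = NA_character_, divergence = d)
  } else { # basal_ambiguous: part-way along the edge above a phylum crown
    ph_node <- node_with_label(tree, rep_tax[2])
    d <- 0.05
    mq <- mutate_from(ph_node, d, d)
    frac <- u01("distal")
    pl <- placement(edge = ph_node,
                    distal_length = frac * tree$edge_length[ph_node],
                    pendant_length = 0.05)
    # truth by nearest-median arithmetic on the generator's depth table:
    # candidate window above a single phylum stack is {phylum, class}
    par_depth <- ref$node_depth[tree$parent[ph_node]]
    red <- par_depth + frac * (ref$node_depth[ph_node] - par_depth)
    win_medians <- c(phylum = ref$rank_depths[["p"]],
                     class = ref$rank_depths[["c"]])
    novel <- names(win_medians)[which.min(abs(red - win_medians))]
    truth_tax[1] <- "d__D1"
    if (novel == "class") truth_tax[2] <- rep_tax[2]
    truth <- list(taxonomy = truth_tax, novel_rank = novel,
                  expected_closest = NA_character_, divergence = d)
  }

  structure(list(id = id, genome = mq$genome, marker_rows = mq$rows,
                 placement = pl, mode = mode, truth = truth),
            class = "synth_query")
}

#' Generate a batch of queries spanning all modes
#'
#' @param reference A [gen_reference()] result.
#' @param n Number of queries.
#' @param seed Master seed; query `i` uses substream seed `seed + i`.
#' @param modes Mode of each query (recycled); defaults to a fixed mixture
#'   of all five modes.
#' @return List of `synth_query` objects with unique ids.
#' @export
gen_queries <- function(reference, n, seed,
                        modes = rep(QUERY_MODES,
                                    times = c(30, 25, 20, 15, 10))) {
  modes <- rep_len(modes, n)
  lapply(seq_len(n), function(i) {
    gen_query(reference, modes[i], seed = as.numeric(seed) * 1000 + i,
              id = sprintf("Q%03d_%s", i, modes[i]))
  })
}

#' Write a reference package to disk
#'
#' Layout: `tree.nwk`, `reference_alignment.fasta` (masked rows),
#' `markers.tsv` (marker, width; row order = concatenation order),
#' `mask.txt`, `radii.tsv`, `genomes/<id>.fasta`.
#'
#' @param reference A [gen_reference()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_reference_package <- function(reference, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  write_newick(reference$tree, file.path(dir, "tree.nwk"))
  write_fasta(reference$ref_alignment,
              file.path(dir, "reference_alignment.fasta"))
  utils::write.table(
    data.frame(marker = reference$marker_order,
               width = unname(reference$marker_widths[reference$marker_order])),
    file.path(dir, "markers.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_mask(reference$mask, file.path(dir, "mask.txt"))
  write_radii(reference$radii, file.path(dir, "radii.tsv"))
  for (g in names(reference$genomes)) {
    write_fasta(stats::setNames(reference$genomes[g], g),
                file.path(dir, "genomes", paste0(g, ".fasta")))
  }
  invisible(dir)
}

#' Write a query set to disk
#'
#' Layout: `genomes/<id>.fasta`, `marker_hits.tsv`, `placements.jplace`
#' (engineered placements), `quality.tsv`, `truth.tsv`.
#'
#' @param queries List of `synth_query` objects (see [gen_queries()]).
#' @param reference The [gen_reference()] result the queries were drawn
#'   from (needed for the jplace tree and marker list).
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_query_set <- function(queries, reference, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  hits <- do.call(rbind, lapply(queries, function(q) {
    data.frame(genome = q$id, marker = reference$marker_order,
               present = as.integer(reference$marker_order %in%
                                      names(q$marker_rows)),
               aligned_row = ifelse(
                 reference$marker_order %in% names(q$marker_rows),
                 q$marker_rows[reference$marker_order], ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(hits, file.path(dir, "marker_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (q in queries) {
    write_fasta(stats::setNames(q$genome, q$id),
                file.path(dir, "genomes", paste0(q$id, ".fasta")))
  }
  pls <- stats::setNames(lapply(queries, function(q) q$placement),
                         vapply(queries, function(q) q$id, character(1)))
  write_jplace(reference$tree, pls, file.path(dir, "placements.jplace"))
  qual <- do.call(rbind, lapply(queries, function(q) {
    s <- substream_seed(reference$spec$seed, paste0("quality/", q$id))
    with_substream(s, "q", data.frame(
      genome = q$id,
      completeness = round(stats::runif(1, 80, 100), 1),
      contamination = round(stats::runif(1, 0, 5), 1),
      stringsAsFactors = FALSE))
  }))
  utils::write.table(qual, file.path(dir, "quality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, lapply(queries, function(q) {
    data.frame(query_id = q$id, mode = q$mode,
               true_taxonomy = format_taxonomy(q$truth$taxonomy),
               novel_rank = ifelse(is.na(q$truth$novel_rank), "",
                                   q$truth$novel_rank),
               expected_closest = ifelse(is.na(q$truth$expected_closest), "",
                                         q$truth$expected_closest),
               divergence = q$truth$divergence, stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
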