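# Shared helpers: random decorated ultrametric trees, a brute-force RED
# oracle (explicit path enumeration, independent of compute_red's
# accumulator recursion), and cached synthetic fixtures.

# random multifurcating ultrametric tree with optional rank decoration
rand_ultra_tree <- function(seed, min_leaves = 4, max_leaves = 16,
                            decorated = FALSE) {
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$parent <- integer(); st$depth <- numeric(); st$leaf <- logical()
  st$taxa <- list(); st$support <- numeric(); st$nleaf <- 0L
  target <- sample(min_leaves:max_leaves, 1)
  add <- function(parent, depth, leaf) {
    k <- length(st$parent) + 1L
    st$parent[k] <- parent; st$depth[k] <- depth; st$leaf[k] <- leaf
    st$taxa[[k]] <- character(); st$support[k] <- NA_real_
    k
  }
  grow <- function(parent, depth, rank, budget) {
    mine <- add(parent, depth, leaf = FALSE)
    if (decorated && rank <= 6 && runif(1) < 0.6) {
      st$taxa[[mine]] <- paste0(c("d", "p", "c", "o", "f", "g")[rank], "__",
                                paste0("T", mine))
      rank <- rank + 1
    }
    if (decorated) st$support[mine] <- round(runif(1, 50, 100), 1)
    nk <- sample(2:3, 1)
    split <- rep(budget %/% nk, nk)
    split[1] <- split[1] + budget %% nk
    for (b in split) {
      if (b <= 1 || depth > 0.8 || runif(1) < 0.25) {
        st$nleaf <- st$nleaf + 1L
        add(mine, 1.0, leaf = TRUE)
      } else {
        grow(mine, depth + runif(1) * (1 - depth) * 0.6, rank, b)
      }
    }
    mine
  }
  grow(NA_integer_, 0, 1, target)
  n <- length(st$parent)
  leaf_name <- ifelse(st$leaf, paste0("L", seq_len(n)), NA_character_)
  edge <- st$depth - ifelse(is.na(st$parent), 0, st$depth[pmax(st$parent, 1)])
  edge[is.na(st$parent)] <- NA_real_
  ref_tree(parent = st$parent, edge_length = edge, leaf_name = leaf_name,
           support = st$support, taxa = st$taxa)
}

# brute-force RED: for every node, enumerate root-free paths explicitly
red_oracle <- function(tr) {
  path_len <- function(from, to) {   # sum of edges walking up to 'from'
    s <- 0; v <- to
    while (v != from) { s <- s + tr$edge_length[v]; v <- tr$parent[v] }
    s
  }
  leaves_below <- function(v) {
    nd <- v; out <- integer()
    while (length(nd)) {
      x <- nd[1]; nd <- nd[-1]
      if (length(tr$children[[x]]) == 0L) out <- c(out, x)
      else nd <- c(nd, tr$children[[x]])
    }
    out
  }
  red <- numeric(tr$n)
  for (v in preorder(tr)) {
    if (v == tr$root) { red[v] <- 0; next }
    if (length(tr$children[[v]]) == 0L) { red[v] <- 1; next }
    p <- tr$parent[v]
    d <- tr$edge_length[v]
    lv <- leaves_below(v)
    u <- mean(vapply(lv, function(l) path_len(p, l), numeric(1)))
    red[v] <- if (u <= 0 || d <= 0) red[p] else red[p] + (d / u) * (1 - red[p])
  }
  red
}

# cached fixtures (generation is deterministic; cache only saves time)
.fx_cache <- new.env(parent = emptyenv())

fixture_small <- function() {
  if (is.null(.fx_cache$small)) {
    spec <- fixture_spec(seed = 7, genome_length = 20000)
    .fx_cache$small <- gen_reference(spec)
  }
  .fx_cache$small
}

fixture_refdata <- function(ref) {
  key <- paste0("refdata_", ref$spec$seed, "_", ref$spec$genome_length)
  if (is.null(.fx_cache[[key]])) {
    red <- compute_red(ref$tree)
    .fx_cache[[key]] <- list(
      tree = ref$tree, redmap = red,
      medians = rank_medians(ref$tree, red),
      ref_alignment = ref$ref_alignment,
      marker_order = ref$marker_order,
      marker_widths = ref$marker_widths,
      mask = ref$mask, radii = ref$radii,
      genomes = as.list(ref$genomes))
  }
  .fx_cache[[key]]
}

# a tiny hand-decorated tree covering stacked labels (sole class in a
# phylum; sole family in an order) used by classify and red tests; every
# root->leaf path is prefix-closed via stacking
hand_tree <- function() {
  txt <- paste0(
    "((((a1:0.2,a2:0.2)'g__Ga':0.3,(b1:0.25,b2:0.25)'g__Gb':0.25)",
    "'o__O1; f__F1':0.2,(c1:0.4,c2:0.4)'o__O2; f__F2; g__Gc':0.3)",
    "'90:p__P1; c__C1':0.3,",
    "((d1:0.3,d2:0.3)'p__P2; c__C2; o__O3; f__F3; g__Gd':0.4,",
    "(e1:0.3,e2:0.3)'p__P3; c__C3; o__O4; f__F4; g__Ge':0.4):0.3)'d__D';")
  read_newick(txt)
}

random_genome <- function(seed, len) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_genome <- function(seq, rate, seed) {
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  pos <- which(runif(n) < rate)
  for (i in pos) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  }
  paste(x, collapse = "")
}
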