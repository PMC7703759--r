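# The decision engine: ancestor taxonomy, candidate windows, RED
# resolution, and the combined rule.

# hand_tree() layout (see helper): phylum P1 holds its sole class C1
# (stacked labels), family F1 with genera Ga/Gb, plus genus Gc directly
# under the class; phyla P2 and P3 hang off an unlabeled node.

graft_at <- function(tr, node, frac = 0.5, qid = "Q") {
  pl <- placement(node, frac * tr$edge_length[node], 0.01)
  c(graft(tr, qid, pl), list(placement = pl))
}

test_that("ancestor_taxonomy unions path labels, prefix-closed", {
  tr <- hand_tree()
  ga <- which(vapply(tr$taxa, function(x) "g__Ga" %in% x, logical(1)))
  g <- graft_at(tr, ga)
  tax <- ancestor_taxonomy(g$tree, g$attachment)
  expect_equal(unname(tax[1:2]), c("d__D", "p__P1"))
  expect_equal(unname(tax[3]), "c__C1")
  expect_equal(unname(tax[5]), "f__F1")
  expect_true(is_prefix_closed(tax))

  # attachment basal to every phylum: only the domain is filled
  un <- which(is.na(tr$leaf_name) & lengths(tr$taxa) == 0L &
                !is.na(tr$parent))
  g2 <- graft_at(tr, un[1])
  tax2 <- ancestor_taxonomy(g2$tree, g2$attachment)
  expect_equal(unname(tax2[1]), "d__D")
  expect_false(any(rank_filled(tax2)[2:7]))
})

test_that("candidate window: distinct taxa below force a single rank", {
  tr <- hand_tree()
  # edge above the unlabeled node joining P2 and P3: window = {phylum}
  un <- which(is.na(tr$leaf_name) & lengths(tr$taxa) == 0L &
                !is.na(tr$parent))
  g <- graft_at(tr, un[1])
  cand <- candidate_ranks(g$tree, g$attachment, g$query_leaf)
  expect_identical(cand$window, 2L)
})

test_that("candidate window: a single crown stack opens a multi-rank window", {
  tr <- hand_tree()
  # edge above the stacked 'p__P1; c__C1' node: novel phylum, novel class,
  # or basal order inside C1 -> window {p, c, o}
  pc <- which(vapply(tr$taxa, function(x) "c__C1" %in% x, logical(1)))
  g <- graft_at(tr, pc)
  cand <- candidate_ranks(g$tree, g$attachment, g$query_leaf)
  expect_identical(cand$window, 2:4)
  expect_equal(unname(cand$crown_taxa[2:3]), c("p__P1", "c__C1"))

  # edge above a genus crown inside a family: window {genus, species}
  ga <- which(vapply(tr$taxa, function(x) "g__Ga" %in% x, logical(1)))
  g2 <- graft_at(tr, ga)
  cand2 <- candidate_ranks(g2$tree, g2$attachment, g2$query_leaf)
  expect_identical(cand2$window, 6:7)
})

test_that("resolve_by_red picks the nearest median, inclusive on ties", {
  med <- c(p = 0.3, c = 0.45, o = 0.62)
  expect_equal(resolve_by_red(3:4, med, 0.60)$rank, 4L)
  expect_equal(resolve_by_red(3:4, med, 0.50)$rank, 3L)
  expect_equal(resolve_by_red(2:4, med, 0.20)$rank, 2L)
  # exact midpoint -> more inclusive rank, with a warning
  tie <- resolve_by_red(3:4, med, (0.45 + 0.62) / 2)
  expect_equal(tie$rank, 3L)
  expect_match(tie$warnings, "tie")
  # missing median -> most inclusive rank, with a warning
  fb <- resolve_by_red(6:7, med, 0.9)
  expect_equal(fb$rank, 6L)
  expect_match(fb$warnings, "falling back")
})

test_that("classify_query: ANI assignment wins and fills the species", {
  tr <- hand_tree()
  red <- compute_red(tr)
  med <- rank_medians(tr, red)
  radii <- data.frame(species_name = c("s__Sa1", "s__Sa2"),
                      representative_genome = c("a1", "a2"),
                      radius_pct = c(95, 95))
  ga <- which(vapply(tr$taxa, function(x) "g__Ga" %in% x, logical(1)))
  pl <- placement(leaf_id(tr, "a1"), 0.1, 0.01)
  ani <- list(structure(list(reference = "a1", ani_pct = 97.1,
                             align_frac = 0.82, warnings = character()),
                        class = "ani_result"),
              structure(list(reference = "a2", ani_pct = 91.0,
                             align_frac = 0.80, warnings = character()),
                        class = "ani_result"))
  res <- classify_query(tr, red, med, pl, ani, radii, "Q")
  expect_equal(res$method, "ANI")
  expect_equal(unname(res$taxonomy[7]), "s__Sa1")
  expect_equal(unname(res$taxonomy[6]), "g__Ga")
  expect_equal(res$closest_reference, "a1")
  expect_equal(res$ani_pct, 97.1)

  # ANI below the radius: novel species within the genus
  ani[[1]]$ani_pct <- 94.2
  res2 <- classify_query(tr, red, med, pl, ani, radii, "Q")
  expect_equal(res2$method, "TOPOLOGY")
  expect_equal(unname(res2$taxonomy[6]), "g__Ga")
  expect_false(rank_filled(res2$taxonomy)[7])
  expect_match(paste(res2$warnings, collapse = " "), "novel species")

  # AF at the threshold fails the strict > rule
  ani[[1]]$ani_pct <- 99.0
  ani[[1]]$align_frac <- 0.60
  ani[[2]]$align_frac <- 0.60
  res3 <- classify_query(tr, red, med, pl, ani, radii, "Q")
  expect_false(rank_filled(res3$taxonomy)[7])
})

test_that("classify_query: topology-only and RED-window paths", {
  tr <- hand_tree()
  red <- compute_red(tr)
  med <- rank_medians(tr, red)
  radii <- data.frame(species_name = character(),
                      representative_genome = character(),
                      radius_pct = numeric())

  # basal to all phyla -> novel phylum by topology
  un <- which(is.na(tr$leaf_name) & lengths(tr$taxa) == 0L &
                !is.na(tr$parent))
  pl <- placement(un[1], 0.5 * tr$edge_length[un[1]], 0.01)
  res <- classify_query(tr, red, med, pl, list(), radii, "Q")
  expect_equal(res$method, "TOPOLOGY")
  expect_equal(unname(res$taxonomy[1]), "d__D")
  expect_false(any(rank_filled(res$taxonomy)[2:7]))
  expect_match(paste(res$warnings, collapse = " "), "novel phylum")

  # above the stacked p/c node: window {p,c,o}; RED decides; a basal-order
  # outcome inherits the stacked phylum and class names
  pc <- which(vapply(tr$taxa, function(x) "c__C1" %in% x, logical(1)))
  pl2 <- placement(pc, 0.99 * tr$edge_length[pc], 0.01)
  qred <- red_at_placement(tr, red, pl2)
  expected_rank <- resolve_by_red(2:4, med, qred)$rank
  res2 <- classify_query(tr, red, med, pl2, list(), radii, "Q")
  expect_equal(res2$method, "RED")
  expect_equal(res2$red_value, qred)
  if (expected_rank == 4L) {
    expect_equal(unname(res2$taxonomy[2:3]), c("p__P1", "c__C1"))
    expect_match(paste(res2$warnings, collapse = " "), "novel order")
  } else {
    expect_false(rank_filled(res2$taxonomy)[expected_rank])
  }
})

test_that("every classification is prefix-closed and deterministic", {
  ref <- fixture_small()
  rd <- fixture_refdata(ref)
  qs <- lapply(c("known_species", "novel_genus", "basal_ambiguous"),
               function(m) gen_query(ref, m, seed = 42))
  for (q in qs) {
    out1 <- classify_one(rd, q$id, q$genome, q$marker_rows,
                         placement = q$placement)
    out2 <- classify_one(rd, q$id, q$genome, q$marker_rows,
                         placement = q$placement)
    expect_true(is_prefix_closed(out1$result$taxonomy))
    expect_identical(summary_frame(list(out1$result)),
                     summary_frame(list(out2$result)))
    if (out1$result$method == "ANI") {
      expect_true(rank_filled(out1$result$taxonomy)[7])
    } else {
      expect_false(rank_filled(out1$result$taxonomy)[7])
    }
  }
})

test_that("candidate_genus finds the ancestor or sibling genus", {
  tr <- hand_tree()
  ga <- which(vapply(tr$taxa, function(x) "g__Ga" %in% x, logical(1)))
  # inside genus Ga (on a leaf edge below the genus crown)
  g <- graft_at(tr, leaf_id(tr, "a1"))
  expect_equal(candidate_genus(g$tree, g$attachment, g$query_leaf), "g__Ga")
  # adjacent: above the genus crown
  g2 <- graft_at(tr, ga)
  expect_equal(candidate_genus(g2$tree, g2$attachment, g2$query_leaf),
               "g__Ga")
  # basal to several phyla: no candidate genus
  un <- which(is.na(tr$leaf_name) & lengths(tr$taxa) == 0L &
                !is.na(tr$parent))
  g3 <- graft_at(tr, un[1])
  expect_true(is.na(candidate_genus(g3$tree, g3$attachment, g3$query_leaf)))
})
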