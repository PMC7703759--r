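# The fixture generator: determinism, internal consistency, calibration.

test_that("gen_reference is deterministic and internally consistent", {
  spec <- fixture_spec(seed = 7, n_phyla = 2, classes_per_phylum = 2,
                       orders_per_class = 1, families_per_order = 1,
                       genera_per_family = 2, species_per_genus = 2,
                       genome_length = 3000)
  ref1 <- gen_reference(spec)
  ref2 <- gen_reference(spec)
  expect_identical(write_newick(ref1$tree), write_newick(ref2$tree))
  expect_identical(ref1$genomes, ref2$genomes)
  expect_identical(ref1$ref_alignment, ref2$ref_alignment)
  expect_identical(ref1$mask, ref2$mask)
  expect_equal(length(ref1$genomes), 2 * 2 * 1 * 1 * 2 * 2)

  # taxonomy strings along every root->leaf path are prefix-closed
  for (g in names(ref1$genomes)) {
    tax <- taxoplace:::leaf_taxonomy(ref1$tree, g)
    expect_true(is_prefix_closed(tax))
    expect_true(all(rank_filled(tax)[1:6]))
  }
  # single-count ranks stack labels (order and family on one node here)
  stacked <- any(vapply(ref1$tree$taxa, function(x)
    any(grepl("^o__", x)) && any(grepl("^f__", x)), logical(1)))
  expect_true(stacked)
})

test_that("conspecific genomes sit inside the species radius", {
  spec <- fixture_spec(seed = 11, n_phyla = 1, classes_per_phylum = 1,
                       orders_per_class = 1, families_per_order = 1,
                       genera_per_family = 2, species_per_genus = 2,
                       genomes_per_species = 2, genome_length = 30000)
  ref <- gen_reference(spec)
  sp <- ref$radii[1, ]
  sp_node <- ref$tree$parent[leaf_id(ref$tree, sp$representative_genome)]
  mates <- leaves_under(ref$tree, sp_node)
  a <- fragment_ani(ref$genomes[[mates[1]]], ref$genomes[[mates[2]]])
  expect_gte(a$ani_pct, sp$radius_pct)
  # congeneric species land outside the radius
  other <- setdiff(ref$radii$representative_genome,
                   sp$representative_genome)[1]
  b <- fragment_ani(ref$genomes[[sp$representative_genome]],
                    ref$genomes[[other]])
  expect_lt(b$ani_pct, sp$radius_pct)
})

test_that("programmed divergence calibrates to ANI within 0.5", {
  ref <- fixture_small()
  for (mode in c("known_species", "novel_species")) {
    q <- gen_query(ref, mode, seed = 17)
    # compare against the representative the query was mutated from
    a <- fragment_ani(q$genome, ref$genomes[[q$truth$expected_closest]])
    expect_lt(abs(a$ani_pct - 100 * (1 - q$truth$divergence)), 0.5)
  }
})

test_that("rank medians of the generated tree are well separated", {
  ref <- fixture_small()
  red <- compute_red(ref$tree)
  med <- rank_medians(ref$tree, red)
  expect_equal(unname(med), unname(ref$rank_depths[c("p", "c", "o", "f",
                                                     "g")]),
               tolerance = 1e-12)
  expect_true(all(diff(unname(med)) >= 0.08))
})

test_that("gen_query is deterministic and respects its mode contract", {
  ref <- fixture_small()
  q1 <- gen_query(ref, "novel_genus", seed = 5)
  q2 <- gen_query(ref, "novel_genus", seed = 5)
  expect_identical(q1$genome, q2$genome)
  expect_identical(q1$marker_rows, q2$marker_rows)
  expect_identical(q1$placement, q2$placement)

  qp <- gen_query(ref, "novel_phylum", seed = 5)
  expect_true(rank_filled(qp$truth$taxonomy)[1])
  expect_false(any(rank_filled(qp$truth$taxonomy)[2:7]))

  expect_error(gen_query(ref, "nonsense", seed = 1),
               class = "taxoplace_validation_error")
  expect_error(fixture_spec(seed = 1, n_phyla = 1, classes_per_phylum = 1,
                            orders_per_class = 1, families_per_order = 1,
                            genera_per_family = 1, species_per_genus = 1),
               class = "taxoplace_validation_error")
  expect_error(fixture_spec(), class = "taxoplace_validation_error")
})

test_that("written packages round-trip through the io layer", {
  ref <- fixture_small()
  td <- withr::local_tempdir()
  write_reference_package(ref, td)
  got <- load_reference_package(td)
  expect_identical(got$tree$leaf_name[tree_leaves(got$tree)],
                   ref$tree$leaf_name[tree_leaves(ref$tree)])
  expect_identical(unname(got$ref_alignment), unname(ref$ref_alignment))
  expect_identical(got$mask, ref$mask)
  expect_equal(got$radii, ref$radii)
  expect_equal(got$domain, "D1")
})
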