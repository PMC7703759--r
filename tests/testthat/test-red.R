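# RED: formula, medians, interpolation.

test_that("RED is pinned at root/leaves and matches hand recursion", {
  tr <- read_newick("(A:1,B:1)r;")
  red <- compute_red(tr)
  expect_equal(unname(red[tr$root]), 0)
  expect_equal(unname(red[tree_leaves(tr)]), c(1, 1))

  # ((A:1,B:1)n1:1,(C:2,D:2)n2:2)root: n1 has d=1, u=mean(2,2)=2 -> 0.5;
  # n2 has d=2, u=mean(4,4)=4 -> 0.5
  tr2 <- read_newick("((A:1,B:1):1,(C:2,D:2):2)r;")
  red2 <- compute_red(tr2)
  internal <- setdiff(seq_len(tr2$n), c(tree_leaves(tr2), tr2$root))
  expect_equal(unname(red2[internal]), c(0.5, 0.5))

  # zero-length internal edge inherits the parent's RED
  tr3 <- read_newick("((A:1,B:1):0,C:1)r;")
  red3 <- compute_red(tr3)
  n1 <- setdiff(seq_len(tr3$n), c(tree_leaves(tr3), tr3$root))
  expect_equal(unname(red3[n1]), unname(red3[tr3$root]))
})

test_that("compute_red validates its input", {
  expect_error(compute_red(read_newick("A;")),
               class = "taxoplace_validation_error")
})

test_that("compute_red agrees with the path-enumeration oracle", {
  for (s in 1:120) {
    tr <- rand_ultra_tree(s, max_leaves = 24)
    expect_equal(as.numeric(compute_red(tr)), red_oracle(tr),
                 tolerance = 1e-12)
  }
})

test_that("RED is monotone and scale invariant", {
  for (s in 1:60) {
    tr <- rand_ultra_tree(s)
    red <- compute_red(tr)
    nonroot <- setdiff(seq_len(tr$n), tr$root)
    expect_true(all(red[nonroot] >= red[tr$parent[nonroot]] - 1e-12))

    tr2 <- tr
    tr2$edge_length <- tr$edge_length * 37.5
    expect_equal(as.numeric(compute_red(tr2)), as.numeric(red),
                 tolerance = 1e-12)
  }
})

test_that("rank_medians takes medians over labeled internal nodes", {
  # three genus-labeled internal nodes with known REDs
  tr <- hand_tree()
  red <- compute_red(tr)
  med <- rank_medians(tr, red)
  g_nodes <- which(vapply(tr$taxa, function(x) any(grepl("^g__", x)),
                          logical(1)))
  expect_equal(unname(med["g"]), median(as.numeric(red[g_nodes])))
  # stacked labels contribute their node's RED at every stacked rank
  c_nodes <- which(vapply(tr$taxa, function(x) any(grepl("^c__", x)),
                          logical(1)))
  expect_equal(unname(med["c"]), median(as.numeric(red[c_nodes])))

  # single labeled node -> its own value; even count -> mean of central two
  tr2 <- read_newick(
    "(((A:1,B:1)'g__G1':1,(C:1,D:1)'g__G2':1)'f__F':1,(E:2,F:2)'g__G3':2)r;")
  red2 <- compute_red(tr2)
  med2 <- rank_medians(tr2, red2)
  g2 <- which(vapply(tr2$taxa, function(x) any(grepl("^g__", x)),
                     logical(1)))
  expect_equal(unname(med2["g"]), median(as.numeric(red2[g2])))
  expect_equal(unname(med2["f"]),
               as.numeric(red2[which(vapply(tr2$taxa, function(x)
                 "f__F" %in% x, logical(1)))]))
})

test_that("red_at_placement interpolates linearly along the edge", {
  tr <- hand_tree()
  red <- compute_red(tr)
  # pick an internal non-root edge
  v <- which(vapply(tr$taxa, function(x) "g__Ga" %in% x, logical(1)))
  p <- tr$parent[v]
  len <- tr$edge_length[v]
  expect_equal(red_at_placement(tr, red, placement(v, 0, 0)),
               as.numeric(red[p]))
  expect_equal(red_at_placement(tr, red, placement(v, len, 0)),
               as.numeric(red[v]))
  expect_equal(red_at_placement(tr, red, placement(v, len / 2, 0)),
               as.numeric(red[p] + (red[v] - red[p]) / 2))
  expect_error(red_at_placement(tr, red, placement(v, len * 2, 0)),
               class = "taxoplace_validation_error")
})

test_that("red table dump has one row per node", {
  tr <- hand_tree()
  red <- compute_red(tr)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_red_table(tr, red, tf)
  df <- utils::read.delim(tf)
  expect_equal(nrow(df), tr$n)
  expect_equal(df$red[tr$root], 0)
})
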