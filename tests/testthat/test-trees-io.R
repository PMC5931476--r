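test_that("parse_newick handles the basic topologies and annotations", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_setequal(t1$tip.label, c("A", "B", "C", "D"))
  expect_equal(nrow(bipartition_set(t1)), 1L)

  star <- parse_newick("(A,B,C);")
  expect_equal(nrow(bipartition_set(star)), 0L)

  t2 <- parse_newick("((A:1,B:2)0.9:3,C:4);")
  expect_setequal(t2$edge.length, c(1, 2, 3, 4))
  sup <- tree_support_values(parse_newick("((A:1,B:2)0.9:3,(C,D));"))
  expect_equal(unname(sup), 0.9)
})

test_that("support is read from comment position when no node label exists", {
  tr <- parse_newick("((A,B)[&support=0.95]:1,(C,D));")
  expect_equal(unname(tree_support_values(tr)), 0.95)
  # node label wins over comment
  tr2 <- parse_newick("((A,B)0.7:1,(C,D));")
  expect_equal(unname(tree_support_values(tr2)), 0.7)
})

test_that("malformed input is rejected with informative errors", {
  expect_error(parse_newick("((A,B),(C,D);"), "unclosed")
  expect_error(parse_newick("((A,B)),C);"), "character")
  expect_error(parse_newick("((A,B),(C,D))"), "terminated")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
  expect_error(parse_newick(";"), "empty")
})

test_that("NEXUS trees blocks with translate tables are read in order", {
  nx <- paste(
    "#NEXUS", "begin trees;",
    " translate", "  1 A,", "  2 B,", "  3 C,", "  4 D;",
    " tree gen.1 = [&U] ((1,2),(3,4));",
    " tree gen.2 = [&U] ((1,3),(2,4));",
    "end;", sep = "\n"
  )
  ts <- parse_nexus_trees(nx, genome_tag = "cpDNA")
  expect_s3_class(ts, "tree_samples")
  expect_length(ts, 2L)
  expect_setequal(ts$trees[[1]]$tip.label, c("A", "B", "C", "D"))
  # order preserved: first tree has AB|CD, second AC|BD
  expect_equal(pkg_keys_as_labels(as_consensus_tree(ts$trees[[1]], 1)), "C|D")
  expect_equal(pkg_keys_as_labels(as_consensus_tree(ts$trees[[2]], 1)), "B|D")
})

test_that("translate and non-translate forms give identical bipartitions", {
  with_tr <- parse_nexus_trees(paste(
    "#NEXUS", "begin trees;",
    " translate 1 A, 2 B, 3 C, 4 D, 5 E;",
    " tree t1 = [&U] (((1,2),3),(4,5));", "end;", sep = "\n"
  ))
  without_tr <- parse_nexus_trees(paste(
    "#NEXUS", "begin trees;",
    " tree t1 = [&U] (((A,B),C),(D,E));", "end;", sep = "\n"
  ))
  expect_setequal(
    oracle_split_keys(with_tr$trees[[1]]),
    oracle_split_keys(without_tr$trees[[1]])
  )
})

test_that("unknown tip tokens are reported by name", {
  nx <- paste(
    "#NEXUS", "begin trees;",
    " translate 1 A, 2 B;",
    " tree t1 = [&U] ((1,2),7);", "end;", sep = "\n"
  )
  expect_error(parse_nexus_trees(nx), "7")
})

test_that("burn-in drops floor(fraction * N) leading trees", {
  mk <- function(n) {
    tree_samples(lapply(seq_len(n), function(i) {
      t <- random_tree(5, seed = i)
      t
    }))
  }
  s1000 <- mk(20)
  expect_length(apply_burnin(s1000, 0.25), 15L)
  expect_length(apply_burnin(mk(7), 0.25), 6L) # floor(1.75) = 1 dropped
  s <- mk(5)
  expect_identical(apply_burnin(s, 0)$trees, s$trees)
  # retained trees are the exact suffix
  b <- apply_burnin(s1000, 0.25)
  expect_identical(
    lapply(b$trees, write_newick),
    lapply(s1000$trees[6:20], write_newick)
  )
  expect_error(apply_burnin(s, 1), "fraction")
  expect_error(apply_burnin(apply_burnin(s, 0.1), 0.1), "already")
})

test_that("newick round trip preserves topology and labels, 4-64 leaves", {
  for (i in 1:20) {
    n <- sample(4:64, 1)
    tr <- random_tree(n, seed = 1000 + i)
    back <- parse_newick(write_newick(tr))
    expect_setequal(back$tip.label, tr$tip.label)
    expect_setequal(oracle_split_keys(back), oracle_split_keys(tr))
  }
  tr <- random_tree(8, seed = 3)
  expect_false(grepl(":", write_newick(tr, include_lengths = FALSE)))
})
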