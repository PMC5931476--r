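test_that("bipartition_set matches edge-cut enumeration on random trees", {
  t6 <- random_tree(6, seed = 1)
  expect_equal(nrow(bipartition_set(t6)), 3L) # n - 3 internal edges
  for (i in 1:10) {
    tr <- random_tree(8, seed = 200 + i)
    expect_setequal(
      pkg_keys_as_labels(as_consensus_tree(tr, 1)),
      oracle_split_keys(tr)
    )
  }
})

test_that("split compatibility agrees with the four-intersection rule", {
  labels <- sprintf("t%02d", 1:8)
  canon_lab <- function(s) if (labels[1] %in% s) setdiff(labels, s) else s
  set.seed(42)
  for (i in 1:50) {
    a <- canon_lab(sort(sample(labels, sample(2:6, 1))))
    b <- canon_lab(sort(sample(labels, sample(2:6, 1))))
    expect_equal(
      splits_compatible(match(a, labels), match(b, labels)),
      oracle_compatible(paste(sort(a), collapse = "|"),
                        paste(sort(b), collapse = "|"),
                        labels)
    )
  }
})

test_that("split frequencies count and pool correctly", {
  ab_cd <- parse_newick("((A,B),(C,D),E);")
  ac_bd <- parse_newick("((A,C),(B,D),E);")
  pop <- tree_samples(list(ab_cd, ab_cd, ab_cd, ac_bd))
  tab <- split_frequencies(pop)
  i <- match("3,4", tab$split) # side {C,D} = split AB|CDE' over sorted universe
  expect_equal(tab$pooled[[i]], 0.75)
  # two populations pooled 1/2, 1/2: f1 = 1, f2 = 0.5 -> 0.75
  p1 <- tree_samples(rep(list(ab_cd), 4), "cp")
  p2 <- tree_samples(c(rep(list(ab_cd), 2), rep(list(ac_bd), 2)), "its")
  tab2 <- split_frequencies(list(p1, p2))
  expect_equal(tab2$pooled[match("3,4", tab2$split)], 0.75)
  # degenerate weights (1, 0) reproduce the single-population table
  tab3 <- split_frequencies(list(p1, p2), weights = c(1, 0))
  tab1 <- split_frequencies(p1)
  expect_equal(
    tab3$pooled[match(tab1$split, tab3$split)],
    tab1$pooled
  )
  # pooling symmetry
  tab_ba <- split_frequencies(list(p2, p1))
  expect_equal(tab2$pooled[order(tab2$split)], tab_ba$pooled[order(tab_ba$split)])
})

test_that("mismatched leaf sets are reported with the symmetric difference", {
  p1 <- tree_samples(list(parse_newick("((A,B),(C,D));")))
  p2 <- tree_samples(list(parse_newick("((A,B),(C,E));")))
  expect_error(split_frequencies(list(p1, p2)), "D.*E|E.*D")
})

test_that("majority-rule consensus matches counting oracle and handles ties", {
  # all trees identical -> that topology, support 1
  tr <- random_tree(7, seed = 5)
  pop <- tree_samples(rep(list(tr), 10))
  cons <- majority_rule_consensus(split_frequencies(pop))
  expect_setequal(pkg_keys_as_labels(cons), oracle_split_keys(tr))
  expect_true(all(cons$edges$support == 1))

  # 60/40 conflict: majority split included at 0.6
  a <- parse_newick("((A,B),(C,D),E);")
  b <- parse_newick("((A,C),(B,D),E);")
  pop2 <- tree_samples(c(rep(list(a), 3), rep(list(b), 2)))
  cons2 <- majority_rule_consensus(split_frequencies(pop2))
  expect_true("3,4" %in% cons2$edges$split)
  expect_equal(cons2$edges$support[cons2$edges$split == "3,4"], 0.6)

  # equal mixture of all 15 five-leaf topologies -> star (every split 3/15)
  all5 <- phangorn::allTrees(5, rooted = FALSE,
                             tip.label = sprintf("t%02d", 1:5))
  cons3 <- majority_rule_consensus(split_frequencies(tree_samples(all5)))
  expect_equal(nrow(cons3$edges), 0L)

  # random populations from exhaustive 5- and 6-leaf topology sets
  for (n in c(5, 6)) {
    all_t <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = sprintf("t%02d", seq_len(n)))
    set.seed(n)
    for (rep in 1:5) {
      idx <- sample(length(all_t), 9, replace = TRUE)
      pop <- tree_samples(all_t[idx])
      cons <- majority_rule_consensus(split_frequencies(pop))
      expect_setequal(
        pkg_keys_as_labels(cons),
        oracle_consensus_splits(pop$trees, "majority")
      )
    }
  }
})

test_that("strict and semi-strict consensus match set-based oracles", {
  t1 <- parse_newick("((A,B),C,D,E);")
  t2 <- parse_newick("(A,B,(C,D),E);")
  semi <- semistrict_consensus(list(t1, t2))
  expect_setequal(pkg_keys_as_labels(semi), c("C|D|E", "C|D"))
  expect_equal(nrow(strict_consensus(list(t1, t2))$edges), 0L)

  conflict <- list(parse_newick("((A,B),(C,D));"), parse_newick("((A,C),(B,D));"))
  expect_equal(nrow(strict_consensus(conflict)$edges), 0L)
  expect_equal(nrow(semistrict_consensus(conflict)$edges), 0L)

  set.seed(7)
  for (rep in 1:8) {
    trees <- lapply(1:3, function(i) random_tree(6, seed = 700 + 10 * rep + i))
    expect_setequal(
      pkg_keys_as_labels(strict_consensus(trees)),
      oracle_consensus_splits(trees, "strict")
    )
    expect_setequal(
      pkg_keys_as_labels(semistrict_consensus(trees)),
      oracle_consensus_splits(trees, "semistrict")
    )
    # identical inputs -> identical topology
    same <- rep(list(trees[[1]]), 3)
    expect_setequal(
      pkg_keys_as_labels(strict_consensus(same)),
      oracle_split_keys(trees[[1]])
    )
  }
})

test_that("consensus outputs are pairwise compatible and MRC contains strict", {
  set.seed(11)
  for (rep in 1:5) {
    trees <- lapply(1:4, function(i) random_tree(7, seed = 900 + 10 * rep + i))
    pop <- tree_samples(trees)
    mrc <- majority_rule_consensus(split_frequencies(pop))
    labels <- sort(trees[[1]]$tip.label)
    keys <- pkg_keys_as_labels(mrc)
    for (i in seq_along(keys)) {
      for (j in seq_along(keys)) {
        expect_true(oracle_compatible(keys[i], keys[j], labels))
      }
    }
    expect_true(all(
      pkg_keys_as_labels(strict_consensus(trees)) %in% keys
    ))
  }
})

test_that("strict consensus agrees with ape::consensus", {
  trees <- lapply(1:4, function(i) random_tree(8, seed = 40 + i))
  ours <- strict_consensus(trees)
  cl <- trees
  class(cl) <- "multiPhylo"
  theirs <- ape::consensus(cl, p = 1)
  expect_setequal(pkg_keys_as_labels(ours), oracle_split_keys(theirs))
})
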