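# Independent oracles used across the suite. These deliberately avoid the
# package's own split machinery: splits are enumerated with ape::prop.part
# and represented as sorted label strings canonicalised on the side that
# excludes the alphabetically first label.

oracle_split_keys <- function(tree) {
  tree <- ape::unroot(tree)
  labels <- sort(tree$tip.label)
  n <- length(labels)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (clade in pp) {
    side <- sort(attr(pp, "labels")[clade])
    if (labels[1] %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(side, collapse = "|"))
    }
  }
  unique(keys)
}

# package split key -> oracle-style label key, for comparison
pkg_keys_as_labels <- function(cons) {
  vapply(cons$edges$leaves, function(L) paste(sort(L), collapse = "|"),
         character(1))
}

oracle_compatible <- function(key1, key2, labels) {
  a <- strsplit(key1, "|", fixed = TRUE)[[1]]
  b <- strsplit(key2, "|", fixed = TRUE)[[1]]
  quads <- list(
    intersect(a, b), setdiff(a, b), setdiff(b, a),
    setdiff(labels, union(a, b))
  )
  any(lengths(quads) == 0)
}

# brute-force consensus by split counting over a tree population
oracle_consensus_splits <- function(trees, rule = c("majority", "strict", "semistrict")) {
  rule <- match.arg(rule)
  labels <- sort(trees[[1]]$tip.label)
  keysets <- lapply(trees, oracle_split_keys)
  all_keys <- unique(unlist(keysets))
  counts <- vapply(all_keys, function(k) {
    sum(vapply(keysets, function(ks) k %in% ks, logical(1)))
  }, numeric(1))
  switch(rule,
    majority = all_keys[counts / length(trees) > 0.5],
    strict = all_keys[counts == length(trees)],
    semistrict = {
      ok <- vapply(all_keys, function(k) {
        all(vapply(all_keys, oracle_compatible, logical(1),
                   key2 = k, labels = labels))
      }, logical(1))
      all_keys[ok]
    }
  )
}

# brute-force Fitch: minimum changes over all internal state assignments,
# for columns of pure A/C/G/T states
oracle_fitch <- function(tree, column) {
  tree <- ape::multi2di(tree, random = FALSE)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  n_int <- tr$Nnode
  states <- c("A", "C", "G", "T")
  leaf_state <- column[tr$tip.label]
  assign_grid <- as.matrix(expand.grid(rep(list(states), n_int),
                                       stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(assign_grid))) {
    st <- c(leaf_state, assign_grid[r, ])
    changes <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

random_column <- function(taxa, seed) {
  set.seed(seed)
  stats::setNames(sample(c("A", "C", "G", "T"), length(taxa), replace = TRUE),
                  taxa)
}

# small deterministic random trees
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

expect_same_splits <- function(cons, oracle_keys) {
  expect_setequal(pkg_keys_as_labels(cons), oracle_keys)
}
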