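#' @title Bipartition (split) algebra
#'
#' @description
#' A bipartition is the pair of complementary leaf sets induced by cutting one
#' edge of an unrooted tree. Splits are stored canonically as the sorted
#' integer indices (into the alphabetically sorted leaf universe) of the side
#' that *excludes* the first leaf of the universe, encoded as a comma-separated
#' key. Two splits over the same universe are equal iff their keys are equal,
#' and — because both canonical sides exclude the reference leaf — two splits
#' are compatible iff their canonical sides are disjoint or nested.
#'
#' @name splits
NULL

split_key <- function(side) paste(side, collapse = ",")

key_to_side <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

#' Canonicalise one side of a split
#'
#' @param side integer indices of the leaves on one side.
#' @param n universe size.
#' @return sorted indices of the side excluding leaf 1.
#' @keywords internal
canonical_side <- function(side, n) {
  side <- sort.int(unique(side))
  if (length(side) && side[1L] == 1L) side <- setdiff(seq_len(n), side)
  side
}

side_is_trivial <- function(side, n) {
  length(side) < 2L || length(side) > n - 2L
}

#' Test compatibility of two canonical splits
#'
#' Both sides exclude the reference leaf, so the four-intersection rule
#' reduces to: compatible iff the sides are disjoint or one contains the
#' other.
#'
#' @param a,b canonical sides (integer vectors) over the same universe.
#' @return logical.
#' @export
splits_compatible <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

#' Extract the non-trivial bipartitions of a tree
#'
#' Treats the tree as unrooted: one split per internal edge, canonicalised
#' over the alphabetically sorted leaf universe. Trees with fewer than four
#' leaves have no non-trivial split and yield an empty set.
#'
#' @param tree a `phylo` object.
#' @param universe optional character vector of leaf labels; must contain the
#'   same labels as the tree (any order). Defaults to `sort(tree$tip.label)`.
#' @param include_trivial also return the trivial (pendant-edge) splits;
#'   used internally for edge-level bookkeeping.
#' @return a tibble with columns `split` (canonical key), `side` (list of
#'   integer indices) and `size` (smaller-side size).
#' @export
bipartition_set <- function(tree, universe = NULL, include_trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(universe)) universe <- sort(tree$tip.label)
  if (!setequal(universe, tree$tip.label) || length(universe) != length(tree$tip.label)) {
    stop("`universe` must contain exactly the tree's leaf labels")
  }
  universe <- sort(universe)
  n <- length(universe)
  keys <- tree_split_keys(tree, universe, include_trivial = include_trivial)
  sides <- lapply(keys, key_to_side)
  tibble::tibble(
    split = keys,
    side = sides,
    size = vapply(sides, function(s) min(length(s), n - length(s)), integer(1))
  )
}

# Fast path: character vector of canonical keys for one tree.
# Used per-tree when counting split frequencies over large tree populations.
tree_split_keys <- function(tree, universe, include_trivial = FALSE) {
  n <- length(universe)
  idx <- match(tree$tip.label, universe)
  if (anyNA(idx)) stop("tree contains leaves absent from the universe")
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tr$edge)
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- idx[i]
  e1 <- tr$edge[, 1L]
  e2 <- tr$edge[, 2L]
  for (r in seq_along(e1)) {
    desc[[e1[r]]] <- c(desc[[e1[r]]], desc[[e2[r]]])
  }
  root <- e1[length(e1)]
  keys <- character(0)
  for (r in seq_along(e1)) {
    v <- e2[r]
    side <- canonical_side(desc[[v]], n)
    if (!include_trivial) {
      # skip trivial splits; also skip the redundant root-edge copy when the
      # root has degree 2 (both root edges cut the same unrooted edge)
      if (side_is_trivial(side, n)) next
    } else if (length(side) == 0L || length(side) == n) {
      next
    }
    keys <- c(keys, split_key(side))
  }
  unique(keys)
}

#' Restrict a canonical split to a smaller leaf universe
#'
#' @param side canonical side over a universe of size `n`.
#' @param n original universe size.
#' @param keep sorted indices (into the original universe) of the leaves kept.
#' @return list with `side` (canonical over the reduced universe, i.e. indices
#'   into `keep`) and `trivial` (logical).
#' @keywords internal
restrict_side <- function(side, n, keep) {
  m <- length(keep)
  new_side <- match(intersect(side, keep), keep)
  new_side <- canonical_side(new_side, m)
  list(side = new_side, trivial = side_is_trivial(new_side, m))
}

#' Build a tree from a set of pairwise compatible splits
#'
#' Constructs the unique tree (rooted, for representation only, on the first
#' leaf of the universe) whose internal edges are exactly the given splits.
#' Unconstrained regions become polytomies; an empty split set gives a star.
#'
#' @param keys character vector of canonical split keys (may be empty).
#' @param universe sorted character vector of leaf labels (length >= 3).
#' @return a `phylo` object; the node carrying each split is recorded in
#'   `attr(,"split_nodes")` (named integer vector, key -> node id).
#' @keywords internal
build_split_tree <- function(keys, universe) {
  n <- length(universe)
  stopifnot(n >= 3L)
  sides <- lapply(keys, key_to_side)
  ord <- order(-lengths(sides), keys)
  sides <- sides[ord]
  keys <- keys[ord]
  # containment forest: clades are nested or disjoint
  top <- 2:n # pseudo-clade holding everything but the reference leaf
  clades <- c(list(top), sides)
  k <- length(clades)
  parent <- integer(k)
  parent[1L] <- 0L
  for (i in seq_len(k)[-1L]) {
    p <- 1L
    for (j in seq_len(i - 1L)) {
      if (all(clades[[i]] %in% clades[[j]]) &&
          length(clades[[j]]) < length(clades[[p]])) {
        p <- j
      }
    }
    parent[i] <- p
  }
  # assign each tip (except the reference) to its smallest containing clade
  tip_parent <- integer(n)
  tip_parent[1L] <- -1L # child of the root
  for (t in 2:n) {
    p <- 1L
    for (j in seq_len(k)) {
      if (t %in% clades[[j]] && length(clades[[j]]) < length(clades[[p]])) p <- j
    }
    tip_parent[t] <- p
  }
  # node ids: tips 1..n, root n+1, clade j -> n+1+j
  n_internal <- 1L + k
  node_of <- function(j) n + 1L + j
  edges <- matrix(0L, 0L, 2L)
  add_edge <- function(p, c) rbind(edges, c(p, c))
  for (j in seq_len(k)) {
    p <- if (parent[j] == 0L) n + 1L else node_of(parent[j])
    edges <- add_edge(p, node_of(j))
  }
  edges <- add_edge(n + 1L, 1L)
  for (t in 2:n) edges <- add_edge(node_of(tip_parent[t]), t)
  tree <- list(
    edge = edges,
    tip.label = universe,
    Nnode = n_internal
  )
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  split_nodes <- if (k > 1L) {
    stats::setNames(vapply(seq_len(k)[-1L], node_of, integer(1)), keys)
  } else {
    stats::setNames(integer(0), character(0))
  }
  attr(tree, "split_nodes") <- split_nodes
  tree
}
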