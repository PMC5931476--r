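#' @title Incongruence detection and classification
#'
#' @description
#' Species whose placements differ between the nuclear and the chloroplast
#' consensus tree with posterior support above a threshold are "hard"
#' incongruences. They are attributed to individual species by a greedy
#' conflict-resolution procedure, their topological displacement is measured
#' on the tree with the species removed, and each species is categorised:
#' a supported conflict spanning a single node is compatible with incomplete
#' lineage sorting, while two or more nodes indicate genomic exchange via
#' hybridisation (chloroplast capture when the plastid marker is the
#' displaced one).
#'
#' @name incongruence
NULL

phylo_of <- function(x) {
  if (inherits(x, "consensus_tree")) x$tree else x
}

#' Coerce a support-annotated tree to a consensus_tree
#'
#' @param tree a `phylo`; numeric internal node labels are read as supports.
#' @param default_support support assigned to edges without a numeric label
#'   (`NA` by default; use 1 for noise-free/known trees).
#' @export
as_consensus_tree <- function(tree, default_support = NA_real_) {
  if (inherits(tree, "consensus_tree")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  universe <- sort(tree$tip.label)
  keys <- tree_split_keys(tree, universe)
  supp <- tree_support_values(tree)
  support <- unname(supp[keys])
  support[is.na(support)] <- default_support
  new_consensus_tree(keys, universe, support)
}

# -- unrooted edge bookkeeping ------------------------------------------------

# One row per edge of the unrooted tree, with its canonical split key
# (trivial pendant splits included). The tree is unrooted first so that every
# edge maps to a distinct split.
edge_split_table <- function(tree) {
  tree <- ape::unroot(ape::collapse.singles(tree))
  universe <- sort(tree$tip.label)
  n <- length(universe)
  idx <- match(tree$tip.label, universe)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tr$edge)
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- idx[i]
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]
  keys <- character(length(e1))
  sides <- vector("list", length(e1))
  for (r in seq_along(e1)) {
    desc[[e1[r]]] <- c(desc[[e1[r]]], desc[[e2[r]]])
  }
  for (r in seq_along(e1)) {
    side <- canonical_side(desc[[e2[r]]], n)
    keys[r] <- split_key(side)
    sides[[r]] <- side
  }
  list(
    tree = tr, universe = universe, parent = e1, child = e2,
    key = keys, side = sides,
    length = if (is.null(tr$edge.length)) NULL else tr$edge.length
  )
}

# BFS distances in the edge-adjacency (line) graph, from a set of edge rows.
edge_graph_distances <- function(est, from_rows) {
  m <- length(est$parent)
  nodes <- max(c(est$parent, est$child))
  incident <- vector("list", nodes)
  for (r in seq_len(m)) {
    incident[[est$parent[r]]] <- c(incident[[est$parent[r]]], r)
    incident[[est$child[r]]] <- c(incident[[est$child[r]]], r)
  }
  dist <- rep(NA_integer_, m)
  dist[from_rows] <- 0L
  frontier <- from_rows
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (r in frontier) {
      nbr <- setdiff(c(incident[[est$parent[r]]], incident[[est$child[r]]]), r)
      new <- nbr[is.na(dist[nbr])]
      dist[new] <- d
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# Attachment of `leaf`: the leaf-set contexts around its attachment node, and
# the matching edge rows in the tree with the leaf removed.
leaf_attachment <- function(tree, leaf) {
  tree <- ape::unroot(ape::collapse.singles(phylo_of(tree)))
  labels <- tree$tip.label
  if (!leaf %in% labels) stop("leaf '", leaf, "' absent from tree")
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(labels)
  tip <- match(leaf, labels)
  row <- which(tr$edge[, 2L] == tip)
  p <- tr$edge[row, 1L]
  # leaf sets of p's neighbour subtrees, excluding the focal leaf
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (r in seq_len(nrow(tr$edge))) {
    desc[[tr$edge[r, 1L]]] <- c(desc[[tr$edge[r, 1L]]], desc[[tr$edge[r, 2L]]])
  }
  child_rows <- which(tr$edge[, 1L] == p & tr$edge[, 2L] != tip)
  contexts <- lapply(child_rows, function(r) labels[desc[[tr$edge[r, 2L]]]])
  parent_row <- which(tr$edge[, 2L] == p)
  if (length(parent_row)) {
    contexts <- c(contexts, list(labels[setdiff(seq_len(n), c(desc[[p]]))]))
  }
  pruned <- ape::drop.tip(tr, leaf)
  est <- edge_split_table(pruned)
  u2 <- est$universe
  ctx_keys <- unique(vapply(contexts, function(L) {
    split_key(canonical_side(match(L, u2), length(u2)))
  }, character(1)))
  rows <- which(est$key %in% ctx_keys)
  list(est = est, rows = rows, contexts = contexts)
}

# Similarity between an edge's split and a context leaf set, both over the
# same reduced universe: best of the two side pairings, as a fraction of
# leaves placed on the matching side.
context_similarity <- function(side, ctx_side, m) {
  inter <- length(intersect(side, ctx_side))
  un <- length(side) + length(ctx_side) - inter
  same <- inter + m - un
  cross <- (length(side) - inter) + (length(ctx_side) - inter)
  max(same, cross) / m
}

#' Topological displacement of one species between two trees
#'
#' Measures how far the attachment point of `species` has moved between two
#' trees over the same leaf set. The species is removed from both trees; in
#' each direction the species' attachment-context split from one tree is
#' matched to the most similar edge of the other tree (maximum side overlap;
#' ties resolved towards the nearest edge), and the displacement is the
#' number of edges the attachment point must cross between that edge and the
#' species' actual attachment edge (distance in the edge-adjacency graph).
#' The maximum of the two directions is returned: 0 means identical
#' placement, 1 a single-node (NNI-scale) shift, and `d >= 2` a deeper
#' regraft.
#'
#' @param tree_a,tree_b `phylo` or `consensus_tree` objects on the same
#'   leaf set (prune to the shared species first).
#' @param species a leaf label present in both.
#' @param details return a list with per-direction distances and the branch
#'   length of the crossed path (when branch lengths exist)?
#' @return an integer (or a list when `details = TRUE`).
#' @export
node_displacement <- function(tree_a, tree_b, species, details = FALSE) {
  ta <- phylo_of(tree_a); tb <- phylo_of(tree_b)
  if (!setequal(ta$tip.label, tb$tip.label)) {
    stop("trees must be over the same leaf set; prune first")
  }
  if (!species %in% ta$tip.label) stop("species '", species, "' missing")
  one_way <- function(src, dst) {
    att_src <- leaf_attachment(src, species)
    att_dst <- leaf_attachment(dst, species)
    est <- att_dst$est
    m <- length(est$universe)
    ctx_sides <- lapply(att_src$contexts, function(L) {
      canonical_side(match(L, est$universe), m)
    })
    sims <- vapply(seq_along(est$key), function(r) {
      max(vapply(ctx_sides, function(cs) {
        context_similarity(est$side[[r]], cs, m)
      }, numeric(1)))
    }, numeric(1))
    best <- which(sims >= max(sims) - 1e-12)
    dist <- edge_graph_distances(est, att_dst$rows)
    d <- min(dist[best])
    path_len <- NA_real_
    if (!is.null(est$length) && is.finite(d) && d >= 2L) {
      # branch length of the intermediate edges crossed
      inter_rows <- which(dist > 0L & dist < d & !is.na(dist))
      # restrict to edges on a shortest path towards one nearest best edge
      tgt <- best[which.min(dist[best])]
      back <- edge_graph_distances(est, tgt)
      on_path <- inter_rows[dist[inter_rows] + back[inter_rows] == d]
      path_len <- sum(est$length[on_path])
    } else if (!is.null(est$length) && is.finite(d)) {
      path_len <- 0
    }
    list(d = as.integer(d), path_len = path_len)
  }
  ab <- one_way(ta, tb)
  ba <- one_way(tb, ta)
  d <- max(ab$d, ba$d)
  if (!details) return(d)
  pl <- c(ab$path_len, ba$path_len)[which.max(c(ab$d, ba$d))]
  list(displacement = d, a_to_b = ab$d, b_to_a = ba$d, path_length = pl)
}

# -- supported conflict -------------------------------------------------------

supported_splits <- function(cons, pp_threshold) {
  stopifnot(inherits(cons, "consensus_tree"))
  if (nrow(cons$edges) && anyNA(cons$edges$support)) {
    stop("consensus tree lacks support annotations")
  }
  e <- cons$edges[cons$edges$support > pp_threshold, , drop = FALSE]
  list(leaves = e$leaves, support = e$support)
}

# label-space split helpers used by the greedy attribution
lab_canonical <- function(set, universe) {
  set <- intersect(universe, set)
  if (length(set) && universe[1] %in% set) set <- setdiff(universe, set)
  sort(set)
}
lab_trivial <- function(set, universe) {
  length(set) < 2L || length(set) > length(universe) - 2L
}
lab_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

# does removing `drop` (character vector) make splits a, b non-conflicting?
pair_resolved_by <- function(a, b, universe, drop) {
  u <- setdiff(universe, drop)
  a2 <- lab_canonical(a, u); b2 <- lab_canonical(b, u)
  lab_trivial(a2, u) || lab_trivial(b2, u) || lab_compatible(a2, b2)
}

#' Supported conflict test for one species
#'
#' True iff the two consensus trees contain incompatible splits, both above
#' the support threshold (`both_sides = FALSE` requires only one side to pass
#' it), whose incompatibility involves the species' position — i.e. removing
#' the species from both splits makes them compatible.
#'
#' @param cons_a,cons_b `consensus_tree` objects (or support-labelled
#'   `phylo`) over the same leaf set.
#' @param species leaf label.
#' @param pp_threshold posterior-probability threshold; the default 0.95
#'   treats PP > 0.95 as supported.
#' @param both_sides must both witnessing splits exceed the threshold?
#' @return list with `conflict` (logical), `min_support` (the weaker support
#'   of the strongest witnessing pair; `NA` if no conflict) and `n_pairs`.
#' @export
supported_conflict <- function(cons_a, cons_b, species, pp_threshold = 0.95,
                               both_sides = TRUE) {
  cons_a <- as_consensus_tree(cons_a)
  cons_b <- as_consensus_tree(cons_b)
  if (!setequal(cons_a$universe, cons_b$universe)) {
    stop("consensus trees are over different leaf sets")
  }
  universe <- cons_a$universe
  sa <- supported_splits(cons_a, -Inf)
  sb <- supported_splits(cons_b, -Inf)
  pairs <- conflict_pairs(sa$leaves, sb$leaves, sa$support, sb$support,
                          universe, species)
  if (nrow(pairs)) {
    pass_a <- sa$support[pairs$i] > pp_threshold
    pass_b <- sb$support[pairs$j] > pp_threshold
    keep <- if (both_sides) pass_a & pass_b else pass_a | pass_b
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    return(list(conflict = FALSE, min_support = NA_real_, n_pairs = 0L))
  }
  list(
    conflict = TRUE,
    min_support = max(pairs$min_support),
    n_pairs = nrow(pairs)
  )
}

conflict_pairs <- function(leaves_a, leaves_b, supp_a, supp_b, universe,
                           species = NULL) {
  out <- list()
  for (i in seq_along(leaves_a)) {
    a <- lab_canonical(leaves_a[[i]], universe)
    for (j in seq_along(leaves_b)) {
      b <- lab_canonical(leaves_b[[j]], universe)
      if (lab_compatible(a, b)) next
      if (!is.null(species) &&
          !pair_resolved_by(leaves_a[[i]], leaves_b[[j]], universe, species)) {
        next
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        i = i, j = j, min_support = min(supp_a[i], supp_b[j])
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(i = integer(0), j = integer(0), min_support = numeric(0))
}

# -- classification -----------------------------------------------------------

# Restrict a consensus tree to a leaf subset (support = max over the original
# splits mapping to each restricted split), optionally renaming a leaf.
restrict_consensus <- function(cons, keep) {
  cons <- as_consensus_tree(cons)
  keep <- sort(intersect(cons$universe, keep))
  if (identical(keep, cons$universe)) return(cons)
  stopifnot(length(keep) >= 3L)
  keys <- character(0); supp <- numeric(0)
  for (i in seq_len(nrow(cons$edges))) {
    side <- lab_canonical(cons$edges$leaves[[i]], keep)
    if (lab_trivial(side, keep)) next
    k <- split_key(match(side, keep))
    pos <- match(k, keys)
    if (is.na(pos)) {
      keys <- c(keys, k); supp <- c(supp, cons$edges$support[i])
    } else {
      supp[pos] <- max(supp[pos], cons$edges$support[i], na.rm = FALSE)
    }
  }
  new_consensus_tree(keys, keep, supp)
}

rename_leaf <- function(cons, old, new) {
  cons <- as_consensus_tree(cons)
  leaves <- lapply(cons$edges$leaves, function(L) {
    L[L == old] <- new
    L
  })
  universe <- sort(c(setdiff(cons$universe, old), new))
  keys <- vapply(leaves, function(L) {
    split_key(lab_canonical(L, universe) |> match(universe))
  }, character(1))
  # re-canonicalisation can merge nothing (bijective relabelling)
  new_consensus_tree(keys, universe, cons$edges$support)
}

#' Classify shared species as congruent, ILS candidates or hybridisation
#' candidates
#'
#' Compares two support-annotated consensus trees. Supported conflicts
#' (splits above `pp_threshold` in both trees that are mutually incompatible)
#' are attributed to species by greedy resolution: repeatedly flag the
#' species whose removal resolves the largest number of outstanding
#' supported conflicts (ties: larger measured displacement, then
#' alphabetical), until no conflict can be resolved by removing a single
#' further species. Each flagged species' displacement is then measured with
#' the other flagged species excluded, and the species is categorised:
#' displacement 1 = `ILS-candidate`, displacement >= 2 =
#' `hybridisation-candidate`.
#'
#' Species with several accessions are collapsed to a single leaf when their
#' accessions are monophyletic in both trees; otherwise each accession is
#' classified separately (suffix kept in the `unit` column).
#'
#' @param cons_a,cons_b the two genomes' consensus trees (`consensus_tree`,
#'   or `phylo` with numeric support labels).
#' @param map optional [build_taxon_map()] result; without it, leaves are
#'   taken as species and the shared set is the leaf intersection.
#' @param pp_threshold support threshold (default 0.95).
#' @param both_sides see [supported_conflict()].
#' @return a tibble of class `incongruence_calls` with one row per
#'   classification unit: `species`, `unit`, `supported_conflict`,
#'   `displacement`, `min_support`, `path_length`, `category`.
#' @export
classify_species <- function(cons_a, cons_b, map = NULL, pp_threshold = 0.95,
                             both_sides = TRUE) {
  cons_a <- as_consensus_tree(cons_a)
  cons_b <- as_consensus_tree(cons_b)
  units <- resolve_units(cons_a, cons_b, map)
  cons_a <- units$cons_a; cons_b <- units$cons_b
  shared <- intersect(cons_a$universe, cons_b$universe)
  if (length(shared) < 4L) stop("need at least 4 shared species")
  cons_a <- restrict_consensus(cons_a, shared)
  cons_b <- restrict_consensus(cons_b, shared)
  shared <- sort(shared)
  sa <- supported_splits(cons_a, pp_threshold)
  sb <- supported_splits(cons_b, pp_threshold)
  ma <- mask_matrix(sa$leaves, shared)
  mb <- mask_matrix(sb$leaves, shared)
  flagged <- character(0)
  repeat {
    keep <- !(shared %in% flagged)
    m <- sum(keep)
    if (m < 4L) break
    a <- dedupe_masks(ma[, keep, drop = FALSE])
    b <- dedupe_masks(mb[, keep, drop = FALSE])
    if (nrow(a) == 0L || nrow(b) == 0L) break
    inc <- incompat_matrix(a, b, m)
    if (!any(inc)) break
    n_res <- vapply(seq_len(m), function(ci) {
      sum(inc & !incompat_matrix(a, b, m, drop_col = ci))
    }, numeric(1))
    names(n_res) <- shared[keep]
    if (max(n_res) == 0) break
    cand <- names(n_res)[n_res == max(n_res)]
    if (length(cand) > 1L) {
      disp <- vapply(cand, function(s) {
        ks <- setdiff(shared, setdiff(flagged, s))
        node_displacement(
          restrict_consensus(cons_a, ks), restrict_consensus(cons_b, ks), s
        )
      }, numeric(1))
      cand <- cand[disp == max(disp)]
    }
    flagged <- c(flagged, sort(cand)[1])
  }
  calls <- purrr::map_dfr(sort(shared), function(s) {
    if (!s %in% flagged) {
      return(tibble::tibble(
        unit = s, supported_conflict = FALSE, displacement = NA_integer_,
        min_support = NA_real_, path_length = NA_real_, category = "congruent"
      ))
    }
    keep <- setdiff(shared, setdiff(flagged, s))
    ra <- restrict_consensus(cons_a, keep)
    rb <- restrict_consensus(cons_b, keep)
    d <- node_displacement(ra, rb, s, details = TRUE)
    sc <- supported_conflict(ra, rb, s, pp_threshold, both_sides)
    if (d$displacement == 0L) {
      return(tibble::tibble(
        unit = s, supported_conflict = FALSE, displacement = 0L,
        min_support = NA_real_, path_length = NA_real_, category = "congruent"
      ))
    }
    tibble::tibble(
      unit = s, supported_conflict = TRUE,
      displacement = as.integer(d$displacement),
      min_support = sc$min_support,
      path_length = d$path_length,
      category = if (d$displacement == 1L) "ILS-candidate" else "hybridisation-candidate"
    )
  })
  calls$species <- units$species_of[calls$unit]
  calls <- calls[, c("species", "unit", "supported_conflict", "displacement",
                     "min_support", "path_length", "category")]
  class(calls) <- c("incongruence_calls", class(calls))
  attr(calls, "pp_threshold") <- pp_threshold
  calls
}

# Collapse monophyletic multi-accession species to single species leaves and
# name the classification units.
resolve_units <- function(cons_a, cons_b, map) {
  if (is.null(map)) {
    labels <- union(cons_a$universe, cons_b$universe)
    return(list(
      cons_a = cons_a, cons_b = cons_b,
      species_of = stats::setNames(labels, labels)
    ))
  }
  genomes <- attr(map, "genomes")
  species_of <- character(0)
  for (g in seq_along(genomes)) {
    cons <- if (g == 1L) cons_a else cons_b
    rows <- map[map$genome == genomes[g], , drop = FALSE]
    keep_names <- stats::setNames(rows$species, rows$accession)
    # default: each accession is its own unit named accession
    for (sp in unique(rows$species)) {
      acc <- rows$accession[rows$species == sp]
      acc <- intersect(acc, cons$universe)
      if (length(acc) == 0L) next
      collapse <- length(acc) == 1L ||
        (is_clade(cons_a, acc_of(map, sp, genomes[1], cons_a)) &&
         is_clade(cons_b, acc_of(map, sp, genomes[2], cons_b)))
      if (collapse) {
        rep_acc <- sort(acc)[1]
        if (length(acc) > 1L) cons <- restrict_consensus(cons, setdiff(cons$universe, setdiff(acc, rep_acc)))
        cons <- rename_leaf(cons, rep_acc, sp)
        species_of[sp] <- sp
      } else {
        for (a in acc) species_of[a] <- sp
      }
    }
    if (g == 1L) cons_a <- cons else cons_b <- cons
  }
  list(cons_a = cons_a, cons_b = cons_b, species_of = species_of)
}

acc_of <- function(map, sp, genome, cons) {
  intersect(map$accession[map$species == sp & map$genome == genome],
            cons$universe)
}

# is `set` one side of some split (or adjacent to a single attachment point)?
is_clade <- function(cons, set) {
  if (length(set) <= 1L) return(TRUE)
  u <- cons$universe
  if (length(set) >= length(u) - 1L) return(TRUE)
  side <- lab_canonical(set, u)
  key <- split_key(match(side, u))
  key %in% cons$edges$split
}

#' @method glance incongruence_calls
#' @export
glance.incongruence_calls <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    congruent = sum(x$category == "congruent"),
    ils_candidate = sum(x$category == "ILS-candidate"),
    hybridisation_candidate = sum(x$category == "hybridisation-candidate"),
    pp_threshold = attr(x, "pp_threshold")
  )
}

#' Attachment context of one leaf
#'
#' Describes where a leaf sits in a tree: the split of the edge it attaches
#' to (after removing the leaf) and the sequence of nested leaf sets
#' ("shells") encountered walking from the leaf towards the root — the
#' sibling set first, then each successive ancestor's additional leaves.
#'
#' @param tree `phylo` or `consensus_tree`.
#' @param leaf leaf label.
#' @return list with `attachment_sides` (leaf-label sides of the attachment
#'   edge(s) in the tree without the leaf) and `shells` (list of character
#'   vectors).
#' @export
attachment_context <- function(tree, leaf) {
  phy <- phylo_of(tree)
  if (!leaf %in% phy$tip.label) stop("leaf '", leaf, "' absent from tree")
  att <- leaf_attachment(phy, leaf)
  tr <- ape::reorder.phylo(phy, "postorder")
  n <- length(tr$tip.label)
  desc <- vector("list", max(tr$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (r in seq_len(nrow(tr$edge))) {
    desc[[tr$edge[r, 1L]]] <- c(desc[[tr$edge[r, 1L]]], desc[[tr$edge[r, 2L]]])
  }
  tip <- match(leaf, tr$tip.label)
  shells <- list()
  v <- tip
  seen <- tip
  repeat {
    row <- which(tr$edge[, 2L] == v)
    if (length(row) == 0L) break
    p <- tr$edge[row, 1L]
    shell <- setdiff(unlist(desc[[p]]), seen)
    shells[[length(shells) + 1L]] <- sort(tr$tip.label[shell[shell <= n]])
    seen <- c(seen, shell)
    v <- p
  }
  shells <- shells[lengths(shells) > 0L]
  list(
    attachment_sides = lapply(att$est$side[att$rows], function(s) {
      att$est$universe[s]
    }),
    shells = shells
  )
}

# -- vectorised split-mask algebra for the greedy attribution ----------------

# rows = splits, cols = leaves of `universe`; entry 1 iff leaf on the stored
# side of the split
mask_matrix <- function(leaf_sets, universe) {
  m <- matrix(0L, length(leaf_sets), length(universe))
  for (i in seq_along(leaf_sets)) {
    m[i, match(intersect(leaf_sets[[i]], universe), universe)] <- 1L
  }
  m
}

# canonicalise rows (side excluding the first kept leaf), drop trivial and
# duplicate restricted splits
dedupe_masks <- function(m) {
  if (nrow(m) == 0L) return(m)
  flip <- m[, 1L] == 1L
  m[flip, ] <- 1L - m[flip, , drop = FALSE]
  sz <- rowSums(m)
  ok <- sz >= 2L & sz <= ncol(m) - 2L
  m <- m[ok, , drop = FALSE]
  if (nrow(m) > 1L) m <- m[!duplicated(apply(m, 1L, paste, collapse = "")), , drop = FALSE]
  m
}

# logical matrix: TRUE where split i of `a` is incompatible with split j of
# `b` (all four intersections non-empty), optionally after dropping one leaf
# column; pairs where either restricted side becomes trivial count as
# compatible
incompat_matrix <- function(a, b, m, drop_col = NULL) {
  if (!is.null(drop_col)) {
    ac <- a[, drop_col]; bc <- b[, drop_col]
    a <- a[, -drop_col, drop = FALSE]
    b <- b[, -drop_col, drop = FALSE]
    m <- m - 1L
  }
  sa <- rowSums(a); sb <- rowSums(b)
  n11 <- a %*% t(b)
  n10 <- sa - n11
  n01 <- matrix(sb, nrow(a), nrow(b), byrow = TRUE) - n11
  n00 <- m - sa - n11 - n01
  inc <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  triv_a <- sa < 2L | sa > m - 2L
  triv_b <- sb < 2L | sb > m - 2L
  inc[triv_a, ] <- FALSE
  inc[, triv_b] <- FALSE
  inc
}
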