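#' Tanglegram of two consensus trees
#'
#' Builds a side-by-side comparison of the two genomes' trees with
#' connecting lines between matching taxa. Leaf orders are optimised to
#' reduce line crossings by seeded hill climbing over internal-node
#' rotations (a fixed iteration budget; crossings never increase). Edges
#' below the support threshold are flagged, and species can be coloured by
#' their incongruence category.
#'
#' @param cons_a,cons_b `consensus_tree` or `phylo` objects.
#' @param map optional [build_taxon_map()]; links then connect accessions of
#'   the same species. Without it, identical leaf labels are linked.
#' @param calls optional [classify_species()] result used for category
#'   colours.
#' @param pp_threshold edges with support below this are flagged.
#' @param iterations rotation hill-climbing budget (total, split over the
#'   two trees).
#' @param seed RNG seed for the rotation proposals.
#' @return object of class `tanglegram`: rotated trees, leaf orders, a
#'   `links` tibble (`leaf_a`, `leaf_b`, `species`, `category`), crossing
#'   counts before/after, and the low-support split keys per tree.
#' @export
tanglegram <- function(cons_a, cons_b, map = NULL, calls = NULL,
                       pp_threshold = 0.95, iterations = 200L, seed = 1L) {
  ta <- phylo_of(as_consensus_tree(cons_a, default_support = 1))
  tb <- phylo_of(as_consensus_tree(cons_b, default_support = 1))
  links <- build_links(ta$tip.label, tb$tip.label, map)
  if (nrow(links) < 2L) stop("need at least 2 shared species to compare")
  set.seed(seed)
  ca <- tree_children(ta)
  cb <- tree_children(tb)
  cross0 <- link_crossings(tip_order(ca), tip_order(cb), links)
  best <- cross0
  half <- max(1L, iterations %/% 2L)
  for (it in seq_len(iterations)) {
    target <- if (it <= half) "a" else "b"
    ch <- if (target == "a") ca else cb
    internals <- which(lengths(ch$children) > 1L)
    v <- internals[sample.int(length(internals), 1L)]
    ch2 <- ch
    kids <- ch2$children[[v]]
    perm <- sample(seq_along(kids))
    ch2$children[[v]] <- kids[perm]
    cr <- if (target == "a") {
      link_crossings(tip_order(ch2), tip_order(cb), links)
    } else {
      link_crossings(tip_order(ca), tip_order(ch2), links)
    }
    if (cr <= best) {
      best <- cr
      if (target == "a") ca <- ch2 else cb <- ch2
    }
  }
  if (!is.null(calls)) {
    links$category <- calls$category[match(links$species, calls$species)]
    links$category[is.na(links$category)] <- "congruent"
  } else {
    links$category <- NA_character_
  }
  low_a <- low_support_splits(cons_a, pp_threshold)
  low_b <- low_support_splits(cons_b, pp_threshold)
  structure(
    list(
      tree_a = ta, tree_b = tb,
      order_a = tip_order(ca), order_b = tip_order(cb),
      children_a = ca, children_b = cb,
      links = links,
      crossings_initial = cross0, crossings = best,
      low_support_a = low_a, low_support_b = low_b,
      pp_threshold = pp_threshold
    ),
    class = "tanglegram"
  )
}

build_links <- function(labels_a, labels_b, map) {
  if (is.null(map)) {
    shared <- intersect(labels_a, labels_b)
    return(tibble::tibble(leaf_a = shared, leaf_b = shared, species = shared))
  }
  genomes <- attr(map, "genomes")
  rows_a <- map[map$genome == genomes[1] & map$accession %in% labels_a, ]
  rows_b <- map[map$genome == genomes[2] & map$accession %in% labels_b, ]
  merged <- dplyr::inner_join(
    rows_a[, c("accession", "species")],
    rows_b[, c("accession", "species")],
    by = "species", suffix = c("_a", "_b"), relationship = "many-to-many"
  )
  tibble::tibble(
    leaf_a = merged$accession_a,
    leaf_b = merged$accession_b,
    species = merged$species
  )
}

# children-list representation preserving a mutable child order
tree_children <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  nn <- max(tr$edge)
  children <- vector("list", nn)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1L]
    children[[p]] <- c(children[[p]], tr$edge[r, 2L])
  }
  list(
    children = children,
    root = length(tr$tip.label) + 1L,
    labels = tr$tip.label,
    n = length(tr$tip.label)
  )
}

tip_order <- function(ch) {
  out <- character(0)
  stack <- ch$root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v <= ch$n) {
      out <- c(out, ch$labels[v])
    } else {
      stack <- c(ch$children[[v]], stack)
    }
  }
  out
}

link_crossings <- function(order_a, order_b, links) {
  pa <- match(links$leaf_a, order_a)
  pb <- match(links$leaf_b, order_b)
  k <- length(pa)
  if (k < 2L) return(0L)
  crossings <- 0L
  for (i in seq_len(k - 1L)) {
    crossings <- crossings +
      sum((pa[i] - pa[(i + 1L):k]) * (pb[i] - pb[(i + 1L):k]) < 0)
  }
  as.integer(crossings)
}

low_support_splits <- function(cons, pp_threshold) {
  if (!inherits(cons, "consensus_tree")) return(character(0))
  e <- cons$edges
  e$split[!is.na(e$support) & e$support < pp_threshold]
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(
    "<tanglegram> ", nrow(x$links), " links, crossings ",
    x$crossings_initial, " -> ", x$crossings, " after untangling\n",
    sep = ""
  )
  invisible(x)
}

#' Write a tanglegram bundle to a directory
#'
#' Emits the two rotated trees as Newick, the links as TSV (with category
#' colours) and the low-support flags.
#'
#' @param tg a [tanglegram()].
#' @param dir output directory.
#' @export
write_tanglegram <- function(tg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(newick_in_order(tg$children_a), file.path(dir, "tree_a.nwk"))
  writeLines(newick_in_order(tg$children_b), file.path(dir, "tree_b.nwk"))
  readr::write_tsv(tg$links, file.path(dir, "links.tsv"))
  writeLines(
    c(paste0("# splits with support < ", tg$pp_threshold),
      paste0("A\t", tg$low_support_a), paste0("B\t", tg$low_support_b)),
    file.path(dir, "low_support.txt")
  )
  invisible(dir)
}

newick_in_order <- function(ch) {
  rec <- function(v) {
    if (v <= ch$n) return(ch$labels[v])
    paste0("(", paste(vapply(ch$children[[v]], rec, character(1)),
                      collapse = ","), ")")
  }
  paste0(rec(ch$root), ";")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot tanglegram
#' @export
autoplot.tanglegram <- function(object, ...) {
  seg_a <- tree_segments(object$children_a, object$order_a, side = -1)
  seg_b <- tree_segments(object$children_b, object$order_b, side = 1)
  ya <- stats::setNames(seq_along(object$order_a), object$order_a)
  yb <- stats::setNames(seq_along(object$order_b), object$order_b)
  links <- dplyr::mutate(
    object$links,
    y_a = ya[.data$leaf_a], y_b = yb[.data$leaf_b],
    category = ifelse(is.na(.data$category), "congruent", .data$category)
  )
  segs <- dplyr::bind_rows(seg_a, seg_b)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0, yend = .data$y1),
      linewidth = 0.3
    ) +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = -0.02, xend = 0.02, y = .data$y_a, yend = .data$y_b,
                   colour = .data$category),
      alpha = 0.7
    ) +
    ggplot2::scale_colour_manual(values = c(
      "congruent" = "grey60", "ILS-candidate" = "goldenrod",
      "hybridisation-candidate" = "firebrick"
    )) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

# layout: depth-proportional x (unit branch lengths), side -1 = left tree
# (drawn towards negative x), +1 = right tree
tree_segments <- function(ch, order, side) {
  ys <- rep(NA_real_, length(ch$children))
  depth <- rep(NA_real_, length(ch$children))
  tip_y <- stats::setNames(seq_along(order), order)
  maxd <- tree_depth(ch$root, ch)
  assign_y <- function(v, d) {
    if (v <= ch$n) {
      ys[v] <<- tip_y[ch$labels[v]]
      depth[v] <<- maxd
      return(ys[v])
    }
    kid_y <- vapply(ch$children[[v]], assign_y, numeric(1), d = d + 1)
    ys[v] <<- mean(kid_y)
    depth[v] <<- d
    ys[v]
  }
  assign_y(ch$root, 0)
  segs <- list()
  xf <- function(d) side * (0.02 + 0.98 * (1 - d / maxd))
  for (v in seq_along(ch$children)) {
    for (k in ch$children[[v]]) {
      segs[[length(segs) + 1L]] <- tibble::tibble(
        x0 = xf(depth[v]), x1 = xf(depth[v]), y0 = ys[v], y1 = ys[k]
      )
      segs[[length(segs) + 1L]] <- tibble::tibble(
        x0 = xf(depth[v]), x1 = xf(depth[k]), y0 = ys[k], y1 = ys[k]
      )
    }
  }
  dplyr::bind_rows(segs)
}

tree_depth <- function(v, ch) {
  if (v <= ch$n) return(0)
  1 + max(vapply(ch$children[[v]], tree_depth, numeric(1), ch = ch))
}
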