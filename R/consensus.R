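#' Pooled bipartition frequencies over one or more tree populations
#'
#' For each population the per-source frequency of a split is the fraction of
#' that population's trees containing it; the pooled frequency is the
#' weighted sum. The default weights give each population equal weight
#' regardless of sample counts, matching the situation where two genomes'
#' post-burn-in runs of equal length are combined.
#'
#' @param populations a single [tree_samples()] object or a list of them
#'   (plain `multiPhylo` objects are accepted and tagged `pop1`, `pop2`, ...).
#'   All populations must share one leaf universe; prune first if not.
#' @param weights numeric pooling weights, one per population, summing to 1.
#'   Default: equal weights.
#' @return a tibble of class `split_freqs` with columns `split`, `side`
#'   (list of integer indices into the sorted universe), one `f_<tag>`
#'   column per population, and `pooled`. The universe is stored in
#'   `attr(, "universe")` and the weights in `attr(, "weights")`.
#' @export
split_frequencies <- function(populations, weights = NULL) {
  if (inherits(populations, "tree_samples")) populations <- list(populations)
  if (inherits(populations, "multiPhylo")) populations <- list(populations)
  populations <- lapply(seq_along(populations), function(i) {
    p <- populations[[i]]
    if (inherits(p, "tree_samples")) return(p)
    tree_samples(p, genome_tag = paste0("pop", i))
  })
  k <- length(populations)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("`weights` must be ", k, " nonnegative values summing to 1")
  }
  universe <- sort(populations[[1]]$trees[[1]]$tip.label)
  for (p in populations) {
    u <- sort(p$trees[[1]]$tip.label)
    if (!identical(u, universe)) {
      stop(
        "populations have mismatched leaf sets; symmetric difference: ",
        paste(union(setdiff(u, universe), setdiff(universe, u)), collapse = ", ")
      )
    }
  }
  tags <- vapply(populations, function(p) p$genome_tag, character(1))
  if (anyDuplicated(tags)) tags <- make.unique(tags, sep = "_")
  per_source <- lapply(populations, function(p) {
    keys <- unlist(lapply(p$trees, tree_split_keys, universe = universe))
    if (length(keys) == 0L) {
      return(stats::setNames(numeric(0), character(0)))
    }
    tab <- table(keys)
    as.numeric(tab) / length(p$trees) -> f
    stats::setNames(f, names(tab))
  })
  all_keys <- sort(unique(unlist(lapply(per_source, names))))
  out <- tibble::tibble(
    split = all_keys,
    side = lapply(all_keys, key_to_side)
  )
  pooled <- rep(0, length(all_keys))
  for (i in seq_len(k)) {
    f <- per_source[[i]][all_keys]
    f[is.na(f)] <- 0
    out[[paste0("f_", tags[i])]] <- as.numeric(f)
    pooled <- pooled + weights[i] * as.numeric(f)
  }
  out$pooled <- pooled
  attr(out, "universe") <- universe
  attr(out, "weights") <- stats::setNames(weights, tags)
  class(out) <- c("split_freqs", class(out))
  out
}

freq_universe <- function(table) {
  u <- attr(table, "universe")
  if (is.null(u)) stop("not a split-frequency table (missing universe)")
  u
}

#' Construct a consensus tree object from split keys
#' @keywords internal
new_consensus_tree <- function(keys, universe, support, ic = NULL) {
  ord <- order(keys)
  keys <- keys[ord]
  support <- support[ord]
  if (!is.null(ic)) ic <- ic[ord]
  tree <- build_split_tree(keys, universe)
  nodes <- attr(tree, "split_nodes")
  tree$node.label <- rep("", tree$Nnode)
  n <- length(universe)
  if (length(keys)) {
    tree$node.label[nodes[keys] - n] <- format(round(support, 4), trim = TRUE)
  }
  edges <- tibble::tibble(
    split = keys,
    leaves = lapply(keys, function(k) universe[key_to_side(k)]),
    support = as.numeric(support),
    ic = if (is.null(ic)) NA_real_ else as.numeric(ic),
    node = if (length(keys)) as.integer(nodes[keys]) else integer(0)
  )
  structure(
    list(tree = tree, edges = edges, universe = universe),
    class = "consensus_tree"
  )
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(
    "<consensus_tree> ", length(x$universe), " leaves, ",
    nrow(x$edges), " internal edges",
    if (!all(is.na(x$edges$ic))) ", IC annotated" else "", "\n",
    sep = ""
  )
  print(x$edges, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy consensus_tree
#' @export
tidy.consensus_tree <- function(x, ...) {
  dplyr::mutate(
    x$edges,
    clade = vapply(.data$leaves, paste, character(1), collapse = ","),
    .keep = "unused"
  )
}

#' Majority-rule consensus from a split-frequency table
#'
#' Includes every non-trivial split whose pooled frequency strictly exceeds
#' the threshold. Splits lying exactly at the threshold (within `tol`) are
#' added greedily in descending frequency (ties broken lexicographically on
#' the canonical key) when compatible with the splits already accepted, so
#' the output is deterministic even for 50/50 conflicts.
#'
#' @param table a [split_frequencies()] table.
#' @param threshold inclusion threshold in `[0.5, 1]`; default 0.5 (the
#'   standard 50% majority rule).
#' @param tol absolute tolerance for "exactly at the threshold".
#' @param strict_greater if `FALSE`, threshold-tied splits are excluded
#'   instead of greedily completed.
#' @return a `consensus_tree`: a `phylo` plus an edge table with per-split
#'   support (pooled frequency).
#' @export
majority_rule_consensus <- function(table, threshold = 0.5, tol = 1e-12,
                                    strict_greater = TRUE) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  universe <- freq_universe(table)
  above <- table$split[table$pooled > threshold + tol]
  accepted <- above
  if (strict_greater) {
    at <- table[abs(table$pooled - threshold) <= tol, , drop = FALSE]
    at <- at[order(-at$pooled, at$split), , drop = FALSE]
    acc_sides <- lapply(accepted, key_to_side)
    for (i in seq_len(nrow(at))) {
      cand <- at$side[[i]]
      if (all(vapply(acc_sides, splits_compatible, logical(1), b = cand))) {
        accepted <- c(accepted, at$split[i])
        acc_sides <- c(acc_sides, list(cand))
      }
    }
  }
  support <- table$pooled[match(accepted, table$split)]
  new_consensus_tree(accepted, universe, support)
}

#' Strict consensus of a set of trees
#'
#' Contains exactly the splits present in every input tree.
#'
#' @param trees a list of `phylo` / `multiPhylo` / [tree_samples()] over a
#'   shared leaf set.
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  universe <- sort(trees[[1]]$tip.label)
  keysets <- lapply(trees, tree_split_keys, universe = universe)
  keys <- Reduce(intersect, keysets)
  new_consensus_tree(keys, universe, rep(1, length(keys)))
}

#' Semi-strict (combinable-component) consensus
#'
#' Contains every split present in at least one input tree and contradicted
#' by no split of any input tree.
#'
#' @inheritParams strict_consensus
#' @export
semistrict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  universe <- sort(trees[[1]]$tip.label)
  keysets <- lapply(trees, tree_split_keys, universe = universe)
  all_keys <- sort(unique(unlist(keysets)))
  sides <- lapply(all_keys, key_to_side)
  ok <- vapply(seq_along(all_keys), function(i) {
    all(vapply(sides, splits_compatible, logical(1), b = sides[[i]]))
  }, logical(1))
  keys <- all_keys[ok]
  freq <- vapply(keys, function(k) {
    mean(vapply(keysets, function(ks) k %in% ks, logical(1)))
  }, numeric(1))
  new_consensus_tree(keys, universe, freq)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "tree_samples")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  ref <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), ref)) {
      stop(
        "trees have mismatched leaf sets; symmetric difference: ",
        paste(
          union(setdiff(t$tip.label, ref), setdiff(ref, t$tip.label)),
          collapse = ", "
        )
      )
    }
  }
  trees
}

#' Internode certainty of one bipartition
#'
#' IC contrasts the pooled frequency of a split with that of its most
#' prevalent incompatible split in the same tree population. With
#' `p1 = f(b) / (f(b) + f(b'))` and `p2 = 1 - p1`,
#' `IC = 1 + p1 log2 p1 + p2 log2 p2` (with `0 log2 0 = 0`). IC is 1 when no
#' conflicting split is observed and 0 when the top conflicting split is
#' equally frequent.
#'
#' @param table a [split_frequencies()] table with pooled frequencies.
#' @param split the focal split: a canonical key, or a character vector of
#'   leaf labels giving one side of the split.
#' @param tol tolerance used when comparing frequencies.
#' @return a single number in `[0, 1]`.
#' @export
#' @examples
#' # two populations in complete conflict -> IC = 0
#' p1 <- tree_samples(rep(list(parse_newick("((A,B),(C,D),E);")), 3), "cp")
#' p2 <- tree_samples(rep(list(parse_newick("((A,C),(B,D),E);")), 3), "its")
#' tab <- split_frequencies(list(p1, p2))
#' internode_certainty(tab, c("A", "B"))
internode_certainty <- function(table, split, tol = 1e-12) {
  universe <- freq_universe(table)
  key <- as_split_key(split, universe)
  i <- match(key, table$split)
  if (is.na(i) || table$pooled[i] <= 0) {
    stop("focal split has pooled frequency 0; IC is undefined")
  }
  side <- table$side[[i]]
  conflicting <- table$pooled[
    !vapply(table$side, splits_compatible, logical(1), b = side) &
      table$pooled > 0
  ]
  if (length(conflicting) == 0L) return(1)
  f1 <- table$pooled[i]
  f2 <- max(conflicting)
  p1 <- f1 / (f1 + f2)
  p2 <- 1 - p1
  plogp <- function(p) if (p < tol) 0 else p * log2(p)
  ic <- 1 + plogp(p1) + plogp(p2)
  min(max(ic, 0), 1)
}

as_split_key <- function(split, universe) {
  if (is.character(split) && length(split) == 1L && grepl("^[0-9,]+$", split)) {
    return(split_key(canonical_side(key_to_side(split), length(universe))))
  }
  idx <- match(split, universe)
  if (anyNA(idx)) {
    stop("unknown leaf labels in split: ", paste(split[is.na(idx)], collapse = ", "))
  }
  split_key(canonical_side(idx, length(universe)))
}

#' Annotate a consensus tree with internode certainty
#'
#' Every split of the consensus must be present in the frequency table
#' (which is automatic when the consensus was built from the same table).
#'
#' @param consensus a `consensus_tree`.
#' @param table a [split_frequencies()] table over the same universe.
#' @return the consensus with an `ic` value per internal edge.
#' @export
annotate_consensus_with_ic <- function(consensus, table) {
  stopifnot(inherits(consensus, "consensus_tree"))
  universe <- freq_universe(table)
  if (!identical(universe, consensus$universe)) {
    stop("consensus and frequency table are over different universes")
  }
  missing <- setdiff(consensus$edges$split, table$split)
  if (length(missing)) {
    stop("consensus split(s) missing from the frequency table: ",
         paste(missing, collapse = "; "))
  }
  consensus$edges$ic <- vapply(
    consensus$edges$split, internode_certainty, numeric(1), table = table
  )
  consensus
}

#' Export a split-frequency table (optionally with IC) as TSV
#'
#' @param table a [split_frequencies()] table.
#' @param path output file.
#' @param with_ic add per-split IC and top-conflict frequency columns.
#' @export
write_split_frequencies <- function(table, path, with_ic = TRUE) {
  universe <- freq_universe(table)
  n <- length(universe)
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    split = vapply(.data$side, function(s) {
      paste(ifelse(seq_len(n) %in% s, "*", "."), collapse = "")
    }, character(1)),
    side = NULL
  )
  if (with_ic) {
    out$top_conflict <- vapply(seq_len(nrow(table)), function(i) {
      conf <- table$pooled[
        !vapply(table$side, splits_compatible, logical(1), b = table$side[[i]])
      ]
      if (length(conf)) max(conf) else 0
    }, numeric(1))
    out$ic <- vapply(table$split, function(k) {
      internode_certainty(table, k)
    }, numeric(1))
  }
  readr::write_tsv(out, path)
  invisible(out)
}
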