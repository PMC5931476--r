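#' @title Fitch parsimony and tree search
#'
#' @description
#' Small-parsimony scoring by the Fitch algorithm with IUPAC ambiguity codes
#' treated as state sets and gaps as missing data (all states), plus an
#' exact parsimony search (exhaustive over all unrooted topologies, feasible
#' up to 9 taxa) and a heuristic search (random stepwise addition with
#' NNI/SPR swapping) for larger taxon sets.
#'
#' @name parsimony
NULL

#' Fitch parsimony length of a tree
#'
#' Sum over included alignment columns of the minimum number of state
#' changes. Polytomies are resolved deterministically (in input order)
#' before scoring; all-missing columns contribute 0.
#'
#' @param tree `phylo` whose tips match the alignment's taxa.
#' @param aln a [alignment()].
#' @return integer tree length.
#' @export
fitch_length <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "dna_alignment"))
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree leaves and alignment taxa differ")
  }
  states <- encode_states(included_matrix(aln))
  sum(fitch_per_column(tree, states))
}

# Vectorised over columns: per-column Fitch change counts for one tree.
# `states` is a taxa x columns integer matrix of IUPAC bit sets.
fitch_per_column <- function(tree, states) {
  if (!ape::is.binary.phylo(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  ncol_s <- ncol(states)
  row_of <- match(tr$tip.label, rownames(states))
  nn <- max(tr$edge)
  S <- matrix(0L, nn, ncol_s)
  S[seq_len(n), ] <- states[row_of, , drop = FALSE]
  counts <- integer(ncol_s)
  first <- rep(TRUE, nn)
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]
  for (r in seq_along(e1)) {
    p <- e1[r]; v <- e2[r]
    if (first[p]) {
      S[p, ] <- S[v, ]
      first[p] <- FALSE
    } else {
      inter <- bitwAnd(S[p, ], S[v, ])
      miss <- inter == 0L
      counts <- counts + miss
      S[p, ] <- ifelse(miss, bitwOr(S[p, ], S[v, ]), inter)
    }
  }
  counts
}

# all unrooted labelled topologies for a taxon set (n <= 9)
all_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 4L, n <= 9L)
  phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
}

#' Parsimony tree search
#'
#' Exact (exhaustive over all unrooted topologies) for 9 or fewer taxa;
#' otherwise heuristic: `n_random_addition` random stepwise-addition starts
#' (via [phangorn::random.addition()]) each swapped to a local optimum with
#' [phangorn::optim.parsimony()], keeping up to `maxtrees` equally best
#' trees. Deterministic given `seed`.
#'
#' @param aln a [alignment()] (>= 4 taxa).
#' @param n_random_addition random-addition replicates (heuristic path);
#'   default 10.
#' @param swap rearrangement used by the heuristic path: `"NNI"` or `"SPR"`.
#' @param maxtrees cap on retained equally best trees; default 100.
#' @param seed RNG seed.
#' @param exact_limit largest taxon count searched exhaustively.
#' @return list with `length` (best Fitch length), `trees` (`multiPhylo` of
#'   best topologies, up to `maxtrees`) and `settings`.
#' @export
parsimony_search <- function(aln, n_random_addition = 10L,
                             swap = c("NNI", "SPR"), maxtrees = 100L,
                             seed = 1L, exact_limit = 9L) {
  swap <- match.arg(swap)
  stopifnot(inherits(aln, "dna_alignment"))
  taxa <- aln$taxa
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  settings <- list(
    method = if (length(taxa) <= exact_limit) "exact" else "heuristic",
    n_random_addition = n_random_addition, swap = swap,
    maxtrees = maxtrees, seed = seed
  )
  if (length(taxa) <= exact_limit) {
    states <- encode_states(included_matrix(aln))
    trees <- all_unrooted_topologies(sort(taxa))
    lens <- vapply(trees, function(t) sum(fitch_per_column(t, states)), numeric(1))
    best <- min(lens)
    keep <- which(lens == best)
    if (length(keep) > maxtrees) keep <- keep[seq_len(maxtrees)]
    bt <- trees[keep]
    class(bt) <- "multiPhylo"
    return(list(length = as.integer(best), trees = bt, settings = settings))
  }
  dat <- phangorn::phyDat(included_matrix(aln), type = "DNA")
  set.seed(seed)
  best_len <- Inf
  best_trees <- list()
  seen <- character(0)
  for (i in seq_len(n_random_addition)) {
    start <- phangorn::random.addition(dat)
    opt <- phangorn::optim.parsimony(
      start, dat, method = "fitch",
      rearrangements = if (swap == "SPR") "SPR" else "NNI",
      trace = 0
    )
    len <- phangorn::parsimony(opt, dat, method = "fitch")
    if (len < best_len) {
      best_len <- len
      best_trees <- list()
      seen <- character(0)
    }
    if (len == best_len && length(best_trees) < maxtrees) {
      key <- paste(sort(tree_split_keys(opt, sort(opt$tip.label))), collapse = ";")
      if (!key %in% seen) {
        seen <- c(seen, key)
        best_trees[[length(best_trees) + 1L]] <- opt
      }
    }
  }
  class(best_trees) <- "multiPhylo"
  list(length = as.integer(best_len), trees = best_trees, settings = settings)
}
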