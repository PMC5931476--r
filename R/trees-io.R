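#' Parse a single Newick string
#'
#' Wraps [ape::read.tree()] with stricter validation and support-value
#' capture. Support values are accepted either as internal node labels
#' (`(A,B)0.95:...`) or as the first numeric value found in a comment
#' attached to an internal node (`(A,B)[&support=0.95]:...`); the node-label
#' form wins when both are present.
#'
#' @param text a Newick string terminated by `";"`.
#' @return a `phylo` object. Numeric internal node labels are retained in
#'   `node.label`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:2)0.9:3,C:4);")
#' tr$node.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || text == ";") stop("empty tree")
  validate_newick_syntax(text)
  text <- promote_comment_support(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("Newick parse error: no tree found")
  validate_tree(tree)
  tree
}

# Cheap syntactic pre-checks so that errors carry a character offset.
validate_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (ch == "[") in_comment <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed parentheses: unmatched ')' at character %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "malformed parentheses: %d unclosed '(' at end of string (length %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";\\s*$", text)) stop("Newick string must be terminated by ';'")
  invisible(TRUE)
}

# Turn ")[&...0.95...]" into ")0.95" when the node has no label of its own,
# so that comment-position supports survive ape's comment stripping.
promote_comment_support <- function(text) {
  gsub("\\)\\[([^]]*?(-?[0-9]+\\.?[0-9]*(?:[eE][-+]?[0-9]+)?)[^]0-9]*)\\]",
       ")\\2", text, perl = TRUE)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative edge lengths")
  }
  tree$tip.label <- trimws(gsub("^['\"]|['\"]$", "", tree$tip.label))
  tree
}

#' Numeric per-edge support values of a tree
#'
#' @param tree a `phylo` with (possibly partial) numeric node labels.
#' @return named numeric vector, canonical split key -> support, covering the
#'   non-trivial splits whose node carries a numeric label.
#' @export
tree_support_values <- function(tree) {
  if (is.null(tree$node.label)) return(stats::setNames(numeric(0), character(0)))
  universe <- sort(tree$tip.label)
  n <- length(universe)
  idx <- match(tree$tip.label, universe)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tr$edge)
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- idx[i]
  vals <- numeric(0)
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]
  for (r in seq_along(e1)) desc[[e1[r]]] <- c(desc[[e1[r]]], desc[[e2[r]]])
  labs <- suppressWarnings(as.numeric(tree$node.label))
  for (r in seq_along(e1)) {
    v <- e2[r]
    if (v <= n) next
    lab <- labs[v - n]
    if (is.na(lab)) next
    side <- canonical_side(desc[[v]], n)
    if (side_is_trivial(side, n)) next
    vals[split_key(side)] <- lab
  }
  vals
}

#' A set of tree samples from one analysis
#'
#' Container for an ordered population of trees from one genome's Bayesian
#' run, with provenance. Order is preserved from the source file because
#' burn-in is a prefix operation.
#'
#' @param trees a `multiPhylo` or list of `phylo`, all over the same leaf set.
#' @param genome_tag short label, e.g. `"cpDNA"` or `"nrITS"`.
#' @param burnin_applied has burn-in already been discarded?
#' @param source optional path of the source file.
#' @return an object of class `tree_samples`.
#' @export
tree_samples <- function(trees, genome_tag = "genome", burnin_applied = FALSE,
                         source = NA_character_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees <- lapply(trees, function(t) {
    stopifnot(inherits(t, "phylo"))
    validate_tree(t)
  })
  if (length(trees) == 0L) stop("empty tree sample set")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      bad <- union(
        setdiff(trees[[i]]$tip.label, ref),
        setdiff(ref, trees[[i]]$tip.label)
      )
      stop(
        "tree ", i, " does not share the common leaf set; differing labels: ",
        paste(bad, collapse = ", ")
      )
    }
  }
  class(trees) <- "multiPhylo"
  structure(
    list(
      trees = trees,
      genome_tag = genome_tag,
      burnin_applied = isTRUE(burnin_applied),
      source = source
    ),
    class = "tree_samples"
  )
}

#' @export
print.tree_samples <- function(x, ...) {
  cat(
    "<tree_samples> ", length(x$trees), " trees, ",
    length(x$trees[[1]]$tip.label), " leaves, genome = ", x$genome_tag,
    if (x$burnin_applied) ", burn-in applied" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.tree_samples <- function(x) length(x$trees)

#' Parse a NEXUS document containing a trees block
#'
#' Accepts MrBayes `.t`-style output: an optional translate table mapping
#' numeric tip tokens to labels, and one `tree <name> = [&U] (...)` statement
#' per sample, in file order.
#'
#' @param text the NEXUS document as a single string, a character vector of
#'   lines, or a file path.
#' @param genome_tag passed to [tree_samples()].
#' @return a [tree_samples()] object.
#' @export
parse_nexus_trees <- function(text, genome_tag = "genome") {
  src <- NA_character_
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    src <- text
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  } else {
    text <- paste(text, collapse = "\n")
  }
  if (!grepl("begin\\s+trees", text, ignore.case = TRUE)) {
    stop("no trees block found in NEXUS document")
  }
  # pull the translate table ourselves so that unknown tokens can be named
  translate <- NULL
  tm <- regmatches(
    text,
    regexpr("(?is)translate\\s+(.*?);", text, perl = TRUE)
  )
  if (length(tm)) {
    body <- sub("(?is)^translate\\s+", "", tm, perl = TRUE)
    body <- sub(";\\s*$", "", body)
    entries <- strsplit(body, ",")[[1]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    tokens <- sub("^(\\S+)\\s+.*$", "\\1", entries)
    labels <- sub("^\\S+\\s+", "", entries)
    labels <- trimws(gsub("^['\"]|['\"]$", "", labels))
    translate <- stats::setNames(labels, tokens)
    # normalise to the one-entry-per-line layout ape::read.nexus expects
    canonical <- paste0(
      "translate\n",
      paste0("\t\t", tokens, " ", labels,
             c(rep(",", length(tokens) - 1L), ";"), collapse = "\n")
    )
    text <- sub("(?is)translate\\s+.*?;", canonical, text, perl = TRUE)
  }
  if (!is.null(translate)) {
    stmts <- regmatches(
      text,
      gregexpr("(?im)^\\s*tree\\s+[^=]+=.*$", text, perl = TRUE)
    )[[1]]
    toks <- unlist(regmatches(
      stmts,
      gregexpr("[(,]\\s*'?([A-Za-z0-9_.-]+)'?\\s*(?=[:,)])", stmts, perl = TRUE)
    ))
    toks <- unique(gsub("^[(,]\\s*'?|'?\\s*$", "", toks))
    unknown <- setdiff(toks, names(translate))
    if (length(unknown)) {
      stop(
        "tip token(s) absent from translate table: ",
        paste(unknown, collapse = ", ")
      )
    }
  }
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(text, tmp)
  trees <- tryCatch(
    ape::read.nexus(tmp),
    error = function(e) stop("NEXUS parse error: ", conditionMessage(e))
  )
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (!is.null(attr(trees, "TipLabel"))) trees <- ape::.uncompressTipLabel(trees)
  tree_samples(unclass(trees), genome_tag = genome_tag, source = src)
}

#' Read tree samples from a file
#'
#' Dispatches on content: NEXUS documents (anything starting with `#NEXUS`)
#' go through [parse_nexus_trees()], everything else is read as a list of
#' `;`-terminated Newick strings, one tree per line.
#'
#' @inheritParams parse_nexus_trees
#' @param path file path.
#' @export
read_tree_samples <- function(path, genome_tag = "genome") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^\\s*#NEXUS", lines[1], ignore.case = TRUE)) {
    out <- parse_nexus_trees(paste(lines, collapse = "\n"), genome_tag)
    out$source <- path
    return(out)
  }
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  tree_samples(trees, genome_tag = genome_tag, source = path)
}

#' Discard burn-in from a sample set
#'
#' Drops the first `floor(fraction * N)` trees. Applying burn-in twice is an
#' error, guarding against double discard.
#'
#' @param samples a [tree_samples()] object.
#' @param fraction burn-in fraction in `[0, 1)`; the default 0.25 discards
#'   the first quarter of samples.
#' @export
#' @examples
#' s <- tree_samples(ape::rmtree(8, 5))
#' length(apply_burnin(s, 0.25)) # 6 trees retained
apply_burnin <- function(samples, fraction = 0.25) {
  stopifnot(inherits(samples, "tree_samples"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 || fraction >= 1) {
    stop("`fraction` must be a single number in [0, 1)")
  }
  if (samples$burnin_applied) {
    stop("burn-in has already been applied to this sample set")
  }
  n <- length(samples$trees)
  drop <- floor(fraction * n)
  kept <- samples$trees[seq.int(drop + 1L, n)]
  class(kept) <- "multiPhylo"
  out <- samples
  out$trees <- kept
  out$burnin_applied <- TRUE
  out
}

#' Write a tree as a Newick string
#'
#' Round-trip stable: `parse_newick(write_newick(t))` preserves the leaf set,
#' topology and retained annotations.
#'
#' @param tree a `phylo`.
#' @param include_support keep internal node labels (support values)?
#' @param include_lengths keep branch lengths?
#' @return a Newick string terminated by `";"`.
#' @export
write_newick <- function(tree, include_support = TRUE, include_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  bad <- grepl("[();,\\[\\]]", tree$tip.label)
  if (any(bad)) {
    quotable <- !grepl("'", tree$tip.label[bad])
    if (any(!quotable)) {
      stop("unquotable leaf labels: ", paste(tree$tip.label[bad][!quotable], collapse = ", "))
    }
    tree$tip.label[bad] <- paste0("'", tree$tip.label[bad], "'")
  }
  if (!include_support) tree$node.label <- NULL
  if (!include_lengths) tree$edge.length <- NULL
  ape::write.tree(tree)
}
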