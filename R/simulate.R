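#' @title Synthetic capture scenarios
#'
#' @description
#' Generates fully specified test worlds for the incongruence pipeline: a
#' species tree (standing in for the nuclear topology), a derived tree with
#' implanted chloroplast-capture events (leaf regrafts at controlled
#' topological displacements), posterior-like tree samples for each genome,
#' alignments evolved on the two topologies, and a truth table recording
#' each event, so recovery can be scored exactly.
#'
#' @name synthetic
NULL

#' Simulate a species tree under a pure-birth (Yule) process
#'
#' @param n_taxa number of species (>= 4).
#' @param seed RNG seed; the result is a pure function of `(n_taxa, seed)`.
#' @return a binary rooted `phylo` with positive branch lengths and leaves
#'   `sp01, sp02, ...`.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 4L) stop("`n_taxa` must be at least 4")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  tree
}

#' Prune one species and regraft it at a chosen topological displacement
#'
#' The species is removed; destination edges of the remaining tree are ranked
#' by their distance (in edges crossed) from the original attachment edge,
#' and one achieving `target_displacement` is drawn at random. Candidate
#' destinations whose resulting conflict could not be attributed back to the
#' moved species (the single-NNI ambiguity where several leaf removals
#' explain the conflict equally well) are rejected, so implanted events are
#' always identifiable from topology alone.
#'
#' @param tree binary `phylo`.
#' @param species leaf to move.
#' @param target_displacement integer >= 1.
#' @param seed RNG seed.
#' @param check_attribution verify that [classify_species()] on the
#'   noise-free pair attributes the conflict uniquely to `species`.
#' @return list with `tree` (the regrafted tree) and `event` (one-row tibble:
#'   species, target and realized displacement, destination split key).
#' @export
inject_capture <- function(tree, species, target_displacement, seed = 1L,
                           check_attribution = TRUE) {
  stopifnot(inherits(tree, "phylo"), target_displacement >= 1L)
  if (!species %in% tree$tip.label) stop("species '", species, "' not in tree")
  if (length(tree$tip.label) < 5L) stop("tree too small to regraft in")
  set.seed(seed)
  att <- leaf_attachment(tree, species)
  est <- att$est
  dist <- edge_graph_distances(est, att$rows)
  cand <- which(dist == target_displacement)
  if (length(cand) == 0L) {
    stop(
      "no destination edge at displacement ", target_displacement,
      "; achievable maximum is ", max(dist, na.rm = TRUE)
    )
  }
  cand <- sample(cand, length(cand))
  pend_len <- stats::median(est$length %||% 1)
  for (r in cand) {
    new_tree <- graft_leaf(est, r, species, pend_len)
    d <- node_displacement(tree, new_tree, species)
    if (d != target_displacement) next
    if (check_attribution && !attribution_unique(tree, new_tree, species)) next
    event <- tibble::tibble(
      species = species,
      target_displacement = as.integer(target_displacement),
      realized_displacement = as.integer(d),
      destination = est$key[r]
    )
    return(list(tree = new_tree, event = event))
  }
  stop(
    "no destination at displacement ", target_displacement,
    " gives a uniquely attributable event for '", species, "'"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

graft_leaf <- function(est, edge_row, label, pend_len) {
  tr <- est$tree
  child <- est$child[edge_row]
  len <- if (is.null(tr$edge.length)) 1 else tr$edge.length[edge_row]
  phytools::bind.tip(
    tr, label,
    edge.length = pend_len,
    where = child, position = len / 2
  )
}

# noise-free identifiability check: the greedy classifier on the pure trees
# must flag exactly the moved species with the realized displacement.
attribution_unique <- function(tree_a, tree_b, species) {
  ca <- as_consensus_tree(tree_a, default_support = 1)
  cb <- as_consensus_tree(tree_b, default_support = 1)
  calls <- tryCatch(
    classify_species(ca, cb, pp_threshold = 0.95),
    error = function(e) NULL
  )
  if (is.null(calls)) return(FALSE)
  flagged <- calls$unit[calls$supported_conflict]
  identical(flagged, species)
}

#' Emulate a posterior sample of trees by per-edge NNI perturbation
#'
#' Each sample starts from the generating topology; every internal edge is,
#' independently with probability `perturb_rate`, re-resolved uniformly among
#' its three NNI configurations (the original and the two alternatives). An
#' edge's split therefore survives a perturbation with probability 1/3, so
#' its expected sample support is `1 - (2/3) * perturb_rate`; all other
#' splits are untouched by an NNI at that edge.
#'
#' @param tree binary `phylo` (the generating topology).
#' @param n_samples number of trees to draw.
#' @param perturb_rate per-edge perturbation probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param genome_tag stored in the resulting [tree_samples()].
#' @return a [tree_samples()] object (burn-in considered already applied).
#' @export
emulate_posterior <- function(tree, n_samples, perturb_rate = 0.05, seed = 1L,
                              genome_tag = "genome") {
  stopifnot(perturb_rate >= 0, perturb_rate < 1)
  tree <- root_at_reference(tree)
  if (!ape::is.binary.phylo(tree)) stop("`tree` must be binary")
  set.seed(seed)
  edges <- internal_edges_rooted(tree)
  samples <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    t <- tree
    if (length(edges) && perturb_rate > 0) {
      hit <- which(stats::runif(length(edges)) < perturb_rate)
      for (v in edges[hit]) {
        t <- nni_resolve(t, v, sample.int(3L, 1L))
      }
    }
    samples[[k]] <- t
  }
  tree_samples(samples, genome_tag = genome_tag, burnin_applied = TRUE)
}

# root (binary) at the pendant edge of the alphabetically first leaf, so the
# rooted representation is canonical and every unrooted-internal edge is an
# edge between two non-root internal nodes.
root_at_reference <- function(tree) {
  ref <- sort(tree$tip.label)[1]
  tree <- ape::unroot(ape::collapse.singles(tree))
  ape::root(tree, outgroup = ref, resolve.root = TRUE)
}

# internal (unrooted sense) edges of a canonically rooted binary tree,
# identified by their child node v: v internal, parent internal and not root.
internal_edges_rooted <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  v <- tree$edge[, 2L]
  p <- tree$edge[, 1L]
  v[v > n & p != root]
}

# replace the resolution around the edge above internal node v:
# choice 1 keeps the tree, 2 and 3 swap one child of v with v's sibling.
nni_resolve <- function(tree, v, choice) {
  if (choice == 1L) return(tree)
  e <- tree$edge
  row_v <- which(e[, 2L] == v)
  u <- e[row_v, 1L]
  sib_row <- which(e[, 1L] == u & e[, 2L] != v)
  child_rows <- which(e[, 1L] == v)
  swap_row <- child_rows[choice - 1L]
  e[sib_row, 1L] <- v
  e[swap_row, 1L] <- u
  tree$edge <- e
  attr(tree, "order") <- NULL
  tree
}

#' Simulate a nucleotide alignment on a tree (Jukes-Cantor)
#'
#' Thin seeded wrapper around [phangorn::simSeq()]: uniform root state,
#' equal-rate substitutions, expected `subst_rate * branch length`
#' substitutions per site per branch.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_columns alignment length.
#' @param subst_rate rate multiplier applied to branch lengths.
#' @param seed RNG seed.
#' @return an [alignment()] object.
#' @export
simulate_alignment <- function(tree, n_columns, subst_rate = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_columns >= 1)
  set.seed(seed)
  if (subst_rate == 0) {
    states <- sample(c("A", "C", "G", "T"), n_columns, replace = TRUE)
    mat <- matrix(rep(states, each = length(tree$tip.label)),
                  nrow = length(tree$tip.label),
                  dimnames = list(tree$tip.label, NULL))
    return(alignment(mat))
  }
  dat <- phangorn::simSeq(tree, l = n_columns, rate = subst_rate)
  mat <- toupper(as.character(dat))
  alignment(mat)
}

#' Scenario configuration
#'
#' Defaults mirror the study system this generator emulates: 49 species, ten
#' single-node (lineage-sorting-scale) events and twenty-two deeper capture
#' events, 500 posterior samples per genome with a 5% per-edge perturbation
#' rate, and ITS-length (853) and plastid-length (6764) alignments.
#'
#' @param n_taxa number of species.
#' @param displacements integer vector, one implanted event per entry; its
#'   values are the target node displacements.
#' @param n_samples posterior samples per genome.
#' @param perturb_rate per-edge NNI perturbation probability.
#' @param accessions_per_species named integer vector (species -> accession
#'   count) or a single integer applied to all species.
#' @param n_columns_a,n_columns_b alignment lengths for the nuclear and
#'   chloroplast partitions.
#' @param subst_rate substitution-rate multiplier for alignment simulation.
#' @param attribution `"strict"` rejection-samples event placements until the
#'   full truth table is exactly recoverable from the noise-free tree pair
#'   (feasible up to moderate event densities; used for calibration);
#'   `"fast"` only verifies each event's own realized displacement, which is
#'   what dense, paper-scale event sets require — at such densities events
#'   interact and per-species attribution is no longer fully identifiable
#'   from topology.
#' @param seed master seed; all stage seeds derive from it.
#' @export
scenario_config <- function(n_taxa = 49L,
                            displacements = c(rep(1L, 10), rep(2L, 11), rep(3L, 11)),
                            n_samples = 500L,
                            perturb_rate = 0.05,
                            accessions_per_species = 1L,
                            n_columns_a = 853L,
                            n_columns_b = 6764L,
                            subst_rate = 0.5,
                            attribution = if (length(displacements) <= 8L) "strict" else "fast",
                            seed = 1L) {
  attribution <- match.arg(attribution, c("strict", "fast"))
  structure(
    list(
      n_taxa = as.integer(n_taxa),
      displacements = as.integer(displacements),
      n_samples = as.integer(n_samples),
      perturb_rate = perturb_rate,
      accessions_per_species = accessions_per_species,
      n_columns_a = as.integer(n_columns_a),
      n_columns_b = as.integer(n_columns_b),
      subst_rate = subst_rate,
      attribution = attribution,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

stage_seed <- function(seed, stage) {
  s <- as.numeric(seed) %% 2147483629
  as.integer((s * 101 + as.numeric(stage) * 7919) %% 2147483629)
}

#' Generate a complete capture scenario
#'
#' Builds the base (nuclear) tree, implants the configured capture events to
#' obtain the derived (chloroplast) tree, emulates posterior samples for both
#' genomes, simulates one alignment per genome, duplicates species into
#' accession leaves where requested, and records the truth table. Movers are
#' redrawn (a bounded number of times) if a drawn combination of events is
#' not jointly attributable from topology.
#'
#' @param config a [scenario_config()].
#' @return a `capture_scenario`: list with `base`, `derived` (trees),
#'   `events` (truth tibble), `samples_a`, `samples_b`, `alignment_a`,
#'   `alignment_b`, `taxon_map`, `truth` and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  n_events <- length(config$displacements)
  if (n_events > config$n_taxa - 4L) stop("more events than regraftable species")
  # events are implanted one at a time: for each requested displacement, try
  # candidate mover species (in seeded order) and destinations until the
  # cumulative truth table is still exactly recoverable from the noise-free
  # tree pair; this keeps every implanted event topologically attributable.
  # if a drawn base tree admits no such placement, a fresh base is drawn.
  base <- NULL
  for (attempt in seq_len(40L)) {
    base <- simulate_species_tree(
      config$n_taxa, stage_seed(config$seed, 1L + 1000L * (attempt - 1L))
    )
    set.seed(stage_seed(config$seed, 2L + 1000L * (attempt - 1L)))
    derived <- base
    events <- list()
    pool <- sample(base$tip.label)
    failed <- FALSE
    for (i in seq_len(n_events)) {
      placed <- FALSE
      for (mover in pool) {
        res <- tryCatch(
          inject_capture(
            derived, mover, config$displacements[i],
            seed = stage_seed(
              config$seed,
              100L + 997L * attempt + 97L * i + match(mover, pool)
            ),
            check_attribution = FALSE
          ),
          error = function(e) NULL
        )
        if (is.null(res)) next
        if (identical(config$attribution, "strict")) {
          cand_events <- dplyr::bind_rows(c(events, list(res$event)))
          if (!scenario_truth_ok(base, res$tree, cand_events)) next
        }
        derived <- res$tree
        events[[length(events) + 1L]] <- res$event
        pool <- setdiff(pool, mover)
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) break
    if (attempt == 40L) {
      stop("could not implant an attributable event set; relax the config")
    }
  }
  events <- if (n_events) dplyr::bind_rows(events) else empty_events()
  if (identical(config$attribution, "fast") && n_events > 0L) {
    # realized displacement is re-measured the way the classifier measures
    # it: between base and derived with the other moved species excluded
    events$realized_displacement <- vapply(events$species, function(s) {
      keep <- setdiff(base$tip.label, setdiff(events$species, s))
      if (length(keep) < 4L) return(NA_integer_)
      node_displacement(
        prune_to_shared(base, keep), prune_to_shared(derived, keep), s
      )
    }, integer(1))
  }
  truth <- dplyr::mutate(
    events,
    category = dplyr::case_when(
      is.na(.data$realized_displacement) ~ NA_character_,
      .data$realized_displacement >= 2L ~ "hybridisation-candidate",
      .data$realized_displacement == 1L ~ "ILS-candidate",
      TRUE ~ "congruent"
    )
  )
  acc <- accession_plan(base$tip.label, config$accessions_per_species)
  base_acc <- add_accessions(base, acc, stage_seed(config$seed, 3L))
  derived_acc <- add_accessions(derived, acc, stage_seed(config$seed, 3L))
  samples_a <- emulate_posterior(
    base_acc, config$n_samples, config$perturb_rate,
    seed = stage_seed(config$seed, 4L), genome_tag = "nrITS"
  )
  samples_b <- emulate_posterior(
    derived_acc, config$n_samples, config$perturb_rate,
    seed = stage_seed(config$seed, 5L), genome_tag = "cpDNA"
  )
  alignment_a <- simulate_alignment(
    base_acc, config$n_columns_a, config$subst_rate, stage_seed(config$seed, 6L)
  )
  alignment_b <- simulate_alignment(
    derived_acc, config$n_columns_b, config$subst_rate, stage_seed(config$seed, 7L)
  )
  map <- dplyr::bind_rows(
    tibble::tibble(
      accession = base_acc$tip.label,
      species = sub("_acc[0-9]+$", "", base_acc$tip.label),
      genome = "nrITS"
    ),
    tibble::tibble(
      accession = derived_acc$tip.label,
      species = sub("_acc[0-9]+$", "", derived_acc$tip.label),
      genome = "cpDNA"
    )
  )
  structure(
    list(
      base = base, derived = derived,
      base_accessions = base_acc, derived_accessions = derived_acc,
      events = events, truth = truth,
      samples_a = samples_a, samples_b = samples_b,
      alignment_a = alignment_a, alignment_b = alignment_b,
      taxon_map = build_taxon_map(map, genome_a = "nrITS", genome_b = "cpDNA"),
      config = config
    ),
    class = "capture_scenario"
  )
}

empty_events <- function() {
  tibble::tibble(
    species = character(0), target_displacement = integer(0),
    realized_displacement = integer(0), destination = character(0)
  )
}

scenario_truth_ok <- function(base, derived, events) {
  ca <- as_consensus_tree(base, default_support = 1)
  cb <- as_consensus_tree(derived, default_support = 1)
  calls <- tryCatch(classify_species(ca, cb), error = function(e) NULL)
  if (is.null(calls)) return(FALSE)
  flagged <- calls[calls$supported_conflict, , drop = FALSE]
  setequal(flagged$unit, events$species) &&
    all(flagged$displacement[match(events$species, flagged$unit)] ==
          events$realized_displacement)
}

accession_plan <- function(species, accessions_per_species) {
  if (length(accessions_per_species) == 1L && is.null(names(accessions_per_species))) {
    k <- rep(as.integer(accessions_per_species), length(species))
    names(k) <- species
  } else {
    k <- rep(1L, length(species))
    names(k) <- species
    k[names(accessions_per_species)] <- as.integer(accessions_per_species)
  }
  k
}

# split selected species leaves into cherries of accession leaves attached by
# short branches (emulating multiple sampled individuals per species)
add_accessions <- function(tree, plan, seed) {
  if (all(plan <= 1L)) return(tree)
  set.seed(seed)
  for (sp in names(plan)[plan > 1L]) {
    k <- plan[[sp]]
    tip <- match(sp, tree$tip.label)
    tree$tip.label[tip] <- paste0(sp, "_acc1")
    for (j in 2:k) {
      where <- match(paste0(sp, "_acc", j - 1L), tree$tip.label)
      tree <- phytools::bind.tip(
        tree, paste0(sp, "_acc", j),
        edge.length = 1e-4, where = where, position = 5e-5
      )
    }
  }
  tree
}

#' @export
print.capture_scenario <- function(x, ...) {
  cat(
    "<capture_scenario> ", x$config$n_taxa, " taxa, ",
    nrow(x$events), " implanted events, ",
    length(x$samples_a), " samples/genome (perturb_rate = ",
    x$config$perturb_rate, ")\n", sep = ""
  )
  if (nrow(x$truth)) print(x$truth)
  invisible(x)
}

#' Write a scenario to a directory of plain-text files
#'
#' Emits `base.nwk`, `derived.nwk`, NEXUS sample files for both genomes,
#' FASTA alignments, `taxon_map.tsv`, `truth.tsv` and `config.json`.
#'
#' @param scenario a `capture_scenario`.
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "capture_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(scenario$base), file.path(dir, "base.nwk"))
  writeLines(write_newick(scenario$derived), file.path(dir, "derived.nwk"))
  ape::write.nexus(scenario$samples_b$trees,
                   file = file.path(dir, "cp_samples.t"), translate = TRUE)
  ape::write.nexus(scenario$samples_a$trees,
                   file = file.path(dir, "its_samples.t"), translate = TRUE)
  write_alignment_fasta(scenario$alignment_a, file.path(dir, "alignment_A.fasta"))
  write_alignment_fasta(scenario$alignment_b, file.path(dir, "alignment_B.fasta"))
  readr::write_tsv(tibble::as_tibble(scenario$taxon_map),
                   file.path(dir, "taxon_map.tsv"))
  readr::write_tsv(scenario$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(
    unclass(scenario$config), file.path(dir, "config.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
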