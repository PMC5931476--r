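#' Pipeline configuration
#'
#' Bundles every stage parameter with the defaults of the analysis this
#' package implements: 25% burn-in, 50% majority-rule consensus, equal
#' pooling weights for the two genomes, a posterior-probability threshold of
#' 0.95 for supported conflict, and 100 ILD permutation replicates.
#'
#' @param samples_a,samples_b tree-sample inputs: file paths or
#'   [tree_samples()] objects (genome A = nuclear, genome B = chloroplast by
#'   convention).
#' @param taxon_map optional path or data frame for [build_taxon_map()].
#' @param alignment_a,alignment_b optional alignments (paths or
#'   [alignment()] objects) for the ILD stage.
#' @param exclude_a,exclude_b exclusion ranges applied to the alignments
#'   (string form, e.g. `"494-548"`).
#' @param burnin burn-in fraction, default 0.25.
#' @param consensus_threshold majority-rule threshold, default 0.5.
#' @param pp_threshold supported-conflict threshold, default 0.95.
#' @param weights pooling weights for the combined consensus, default equal.
#' @param ild_replicates ILD permutation replicates, default 100.
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @export
pipeline_config <- function(samples_a = NULL, samples_b = NULL,
                            taxon_map = NULL,
                            alignment_a = NULL, alignment_b = NULL,
                            exclude_a = NULL, exclude_b = NULL,
                            burnin = 0.25,
                            consensus_threshold = 0.5,
                            pp_threshold = 0.95,
                            weights = c(0.5, 0.5),
                            ild_replicates = 100L,
                            seed = 1L,
                            out_dir = NULL) {
  structure(
    list(
      samples_a = samples_a, samples_b = samples_b,
      taxon_map = taxon_map,
      alignment_a = alignment_a, alignment_b = alignment_b,
      exclude_a = exclude_a, exclude_b = exclude_b,
      burnin = burnin,
      consensus_threshold = consensus_threshold,
      pp_threshold = pp_threshold,
      weights = weights,
      ild_replicates = as.integer(ild_replicates),
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

resolve_samples <- function(x, tag) {
  if (inherits(x, "tree_samples")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_tree_samples(x, genome_tag = tag))
  }
  stop("cannot interpret tree-sample input for ", tag)
}

resolve_alignment <- function(x) {
  if (inherits(x, "dna_alignment")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_alignment(x))
  stop("cannot interpret alignment input")
}

#' Run the full incongruence pipeline
#'
#' Stages: burn-in on both genomes' samples, aggregation of accessions to
#' species, pruning to the shared species set, per-genome majority-rule
#' consensus, pooled consensus with internode certainty, supported-conflict
#' detection and species classification, and a tanglegram. When
#' `config$out_dir` is set, the calls TSV, the IC-annotated trees, a JSON
#' summary and a parameter log are written there (byte-identical across
#' reruns with the same inputs and config).
#'
#' @param config a [pipeline_config()].
#' @return list with `consensus_a`, `consensus_b`, `combined` (IC-annotated
#'   pooled consensus), `frequencies`, `calls`, `summary`, `tanglegram`.
#' @export
run_incongruence_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sa <- resolve_samples(config$samples_a, "nrITS")
  sb <- resolve_samples(config$samples_b, "cpDNA")
  if (!sa$burnin_applied) sa <- apply_burnin(sa, config$burnin)
  if (!sb$burnin_applied) sb <- apply_burnin(sb, config$burnin)
  map <- if (!is.null(config$taxon_map)) {
    build_taxon_map(config$taxon_map,
                    labels_a = sa$trees[[1]]$tip.label,
                    labels_b = sb$trees[[1]]$tip.label)
  } else NULL
  # aggregate accessions to species leaves per genome, then prune to shared
  agg <- aggregate_samples(sa, sb, map)
  sa <- agg$a; sb <- agg$b
  shared <- intersect(sa$trees[[1]]$tip.label, sb$trees[[1]]$tip.label)
  if (length(shared) < 4L) stop("fewer than 4 shared species after mapping")
  sa <- prune_samples(sa, shared)
  sb <- prune_samples(sb, shared)
  freq_a <- split_frequencies(sa)
  freq_b <- split_frequencies(sb)
  cons_a <- majority_rule_consensus(freq_a, config$consensus_threshold)
  cons_b <- majority_rule_consensus(freq_b, config$consensus_threshold)
  pooled <- split_frequencies(list(sa, sb), weights = config$weights)
  combined <- majority_rule_consensus(pooled, config$consensus_threshold)
  combined <- annotate_consensus_with_ic(combined, pooled)
  calls <- classify_species(cons_a, cons_b, pp_threshold = config$pp_threshold)
  summary <- glance(calls)
  tg <- tanglegram(cons_a, cons_b, calls = calls,
                   pp_threshold = config$pp_threshold, seed = config$seed)
  result <- list(
    consensus_a = cons_a, consensus_b = cons_b,
    combined = combined, frequencies = pooled,
    calls = calls, summary = summary, tanglegram = tg,
    config = config
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

aggregate_samples <- function(sa, sb, map) {
  if (is.null(map)) return(list(a = sa, b = sb))
  genomes <- attr(map, "genomes")
  agg_one <- function(s, genome) {
    labels <- s$trees[[1]]$tip.label
    rows <- map[map$genome == genome & map$accession %in% labels, ]
    # one representative accession per species; extra accessions dropped
    reps <- dplyr::summarise(
      dplyr::group_by(rows, .data$species),
      rep_acc = sort(.data$accession)[1], .groups = "drop"
    )
    keep <- reps$rep_acc
    rename <- stats::setNames(reps$species, reps$rep_acc)
    trees <- lapply(s$trees, function(t) {
      t <- ape::keep.tip(t, keep)
      t$tip.label <- unname(rename[t$tip.label])
      t
    })
    tree_samples(trees, s$genome_tag, burnin_applied = s$burnin_applied,
                 source = s$source)
  }
  list(a = agg_one(sa, genomes[1]), b = agg_one(sb, genomes[2]))
}

prune_samples <- function(s, keep) {
  if (setequal(keep, s$trees[[1]]$tip.label)) return(s)
  trees <- lapply(s$trees, prune_to_shared, keep = keep)
  tree_samples(trees, s$genome_tag, burnin_applied = s$burnin_applied,
               source = s$source)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  readr::write_tsv(tibble::as_tibble(result$calls), p("calls.tsv"))
  writeLines(consensus_newick(result$consensus_a), p("consensus_a.nwk"))
  writeLines(consensus_newick(result$consensus_b), p("consensus_b.nwk"))
  writeLines(consensus_newick(result$combined), p("combined_ic.nwk"))
  write_split_frequencies(result$frequencies, p("split_frequencies.tsv"))
  jsonlite::write_json(
    as.list(result$summary), p("summary.json"), auto_unbox = TRUE, digits = NA
  )
  write_tanglegram(result$tanglegram, p("tanglegram"))
  log <- c(
    "incongruence pipeline parameters",
    paste0("burnin_fraction\t", config$burnin),
    paste0("consensus_threshold\t", config$consensus_threshold),
    paste0("pp_threshold\t", config$pp_threshold),
    paste0("pooling_weights\t", paste(config$weights, collapse = ",")),
    paste0("seed\t", config$seed),
    paste0("n_calls\t", nrow(result$calls))
  )
  writeLines(log, p("pipeline_log.txt"))
  invisible(config$out_dir)
}

#' Newick string of a consensus tree with support/IC comment annotations
#' @param cons a `consensus_tree`.
#' @export
consensus_newick <- function(cons) {
  stopifnot(inherits(cons, "consensus_tree"))
  tree <- cons$tree
  labs <- rep("", tree$Nnode)
  n <- length(cons$universe)
  for (i in seq_len(nrow(cons$edges))) {
    node <- cons$edges$node[i]
    ann <- sprintf("[&support=%.4g", cons$edges$support[i])
    if (!is.na(cons$edges$ic[i])) {
      ann <- paste0(ann, sprintf(",ic=%.4g", cons$edges$ic[i]))
    }
    labs[node - n] <- paste0(ann, "]")
  }
  tree$node.label <- labs
  txt <- ape::write.tree(tree)
  # ape quotes labels containing brackets; strip the quotes back off
  gsub("'(\\[&[^']*\\])'", "\\1", txt)
}

#' Run the ILD stage
#'
#' Reads the two alignments, applies the configured exclusion ranges and
#' runs [ild_test()] with the configured replicate count and seed. Results
#' are written as JSON plus a per-replicate TSV when `out_dir` is set.
#'
#' @param config a [pipeline_config()] with alignments set.
#' @return an `ild_result`.
#' @export
run_ild <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  a <- resolve_alignment(config$alignment_a)
  b <- resolve_alignment(config$alignment_b)
  if (!is.null(config$exclude_a)) a <- apply_exclusion_ranges(a, config$exclude_a)
  if (!is.null(config$exclude_b)) b <- apply_exclusion_ranges(b, config$exclude_b)
  res <- ild_test(a, b, replicates = config$ild_replicates, seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        d_obs = res$d_obs, p_value = res$p_value, p_raw = res$p_raw,
        lengths = as.list(res$lengths), replicates = res$replicates,
        seed = res$seed, settings = res$settings
      ),
      file.path(config$out_dir, "ild.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_tsv(tidy(res), file.path(config$out_dir, "ild_replicates.tsv"))
  }
  res
}

#' Simulation study over a grid of scenario configurations
#'
#' For each grid cell, generates scenarios, runs the sample-based pipeline
#' (per-genome majority-rule consensus from the emulated posteriors,
#' classification at the configured threshold) and scores recovery of the
#' implanted events, the false-positive rate among unmanipulated species,
#' and the mean internode certainty at implanted-conflict versus undisturbed
#' splits of the pooled consensus.
#'
#' @param grid a data frame with columns among `n_taxa`, `n_events`,
#'   `perturb_rate`, `n_samples`, `n_reps` (scenario replicates per cell);
#'   missing columns get defaults.
#' @param displacement_pool displacements drawn (cyclically) for implanted
#'   events.
#' @param pp_threshold classification threshold.
#' @param seed master seed.
#' @return a tibble with one row per cell: recovery rate (implanted
#'   displacement >= 2 events called hybridisation candidates), ILS recovery,
#'   false-positive rate, and mean IC at disturbed/undisturbed splits.
#' @export
run_simulation_study <- function(grid, displacement_pool = c(2L, 3L),
                                 pp_threshold = 0.95, seed = 1L) {
  grid <- tibble::as_tibble(grid)
  defaults <- list(n_taxa = 12L, n_events = 2L, perturb_rate = 0.05,
                   n_samples = 100L, n_reps = 5L)
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    res <- purrr::map_dfr(seq_len(cell$n_reps), function(r) {
      score_scenario_cell(cell, displacement_pool, pp_threshold,
                          stage_seed(seed, i * 1000L + r))
    })
    tibble::tibble(
      n_taxa = cell$n_taxa, n_events = cell$n_events,
      perturb_rate = cell$perturb_rate, n_samples = cell$n_samples,
      n_reps = cell$n_reps,
      recovery_hyb = mean(res$recovery_hyb, na.rm = TRUE),
      recovery_ils = mean(res$recovery_ils, na.rm = TRUE),
      fpr = mean(res$fpr, na.rm = TRUE),
      mean_ic_disturbed = mean(res$ic_disturbed, na.rm = TRUE),
      mean_ic_undisturbed = mean(res$ic_undisturbed, na.rm = TRUE)
    )
  })
}

score_scenario_cell <- function(cell, displacement_pool, pp_threshold, seed) {
  disp <- rep(displacement_pool, length.out = cell$n_events)
  cfg <- scenario_config(
    n_taxa = cell$n_taxa, displacements = disp,
    n_samples = cell$n_samples, perturb_rate = cell$perturb_rate,
    n_columns_a = 10L, n_columns_b = 10L, seed = seed
  )
  sc <- generate_scenario(cfg)
  scr <- score_scenario(sc, pp_threshold)
  tibble::as_tibble(scr)
}

#' Score classification recovery on one scenario
#'
#' @param scenario a `capture_scenario`.
#' @param pp_threshold classification threshold.
#' @return list with recovery and false-positive rates and IC summaries.
#' @export
score_scenario <- function(scenario, pp_threshold = 0.95) {
  freq_a <- split_frequencies(scenario$samples_a)
  freq_b <- split_frequencies(scenario$samples_b)
  cons_a <- majority_rule_consensus(freq_a)
  cons_b <- majority_rule_consensus(freq_b)
  calls <- classify_species(cons_a, cons_b, pp_threshold = pp_threshold)
  truth <- scenario$truth
  hyb_truth <- truth$species[truth$realized_displacement >= 2L]
  ils_truth <- truth$species[truth$realized_displacement == 1L]
  negatives <- setdiff(calls$species, truth$species)
  called <- function(sp) calls$category[match(sp, calls$species)]
  pooled <- split_frequencies(list(scenario$samples_a, scenario$samples_b))
  base_keys <- tree_split_keys(scenario$base_accessions,
                               sort(scenario$base_accessions$tip.label))
  derived_keys <- tree_split_keys(scenario$derived_accessions,
                                  sort(scenario$derived_accessions$tip.label))
  disturbed <- union(setdiff(base_keys, derived_keys),
                     setdiff(derived_keys, base_keys))
  undisturbed <- intersect(base_keys, derived_keys)
  ic_of <- function(keys) {
    keys <- intersect(keys, pooled$split[pooled$pooled > 0])
    if (!length(keys)) return(NA_real_)
    mean(vapply(keys, internode_certainty, numeric(1), table = pooled))
  }
  list(
    recovery_hyb = if (length(hyb_truth))
      mean(called(hyb_truth) == "hybridisation-candidate") else NA_real_,
    recovery_ils = if (length(ils_truth))
      mean(called(ils_truth) == "ILS-candidate") else NA_real_,
    fpr = if (length(negatives))
      mean(called(negatives) != "congruent") else NA_real_,
    ic_disturbed = ic_of(disturbed),
    ic_undisturbed = ic_of(undisturbed),
    n_calls = nrow(calls)
  )
}
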