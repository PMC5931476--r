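test_that("species-tree simulation is seeded and produces valid trees", {
  tr <- simulate_species_tree(4, seed = 1)
  expect_equal(nrow(bipartition_set(tr)), 1L)
  expect_true(all(tr$edge.length > 0))
  expect_error(simulate_species_tree(3), "at least 4")
  expect_identical(
    write_newick(simulate_species_tree(9, seed = 7)),
    write_newick(simulate_species_tree(9, seed = 7))
  )
})

test_that("five-taxon draws cover all 15 unrooted topologies", {
  seen <- character(0)
  for (i in 1:1000) {
    tr <- simulate_species_tree(5, seed = 10000 + i)
    seen <- union(seen, paste(sort(oracle_split_keys(tr)), collapse = ";"))
  }
  expect_equal(length(seen), 15L)
})

test_that("posterior emulation at rate 0 reproduces the generating topology", {
  tr <- simulate_species_tree(9, seed = 2)
  s <- emulate_posterior(tr, 25, perturb_rate = 0, seed = 3)
  expect_length(s, 25L)
  keys <- oracle_split_keys(tr)
  for (t in s$trees) expect_setequal(oracle_split_keys(t), keys)
})

test_that("per-edge split support matches 1 - (2/3) * perturb_rate", {
  tr <- simulate_species_tree(8, seed = 5)
  rate <- 0.3
  s <- emulate_posterior(tr, 2000, perturb_rate = rate, seed = 6)
  tab <- split_frequencies(s)
  gen_keys <- vapply(
    bipartition_set(tr)$side, function(x) paste(x, collapse = ","), character(1)
  )
  obs <- tab$pooled[match(gen_keys, tab$split)]
  expect_true(all(abs(obs - (1 - 2 / 3 * rate)) < 0.03))
})

test_that("consensus of moderately noisy samples recovers the topology", {
  tr <- simulate_species_tree(10, seed = 8)
  s <- emulate_posterior(tr, 300, perturb_rate = 0.1, seed = 9)
  cons <- majority_rule_consensus(split_frequencies(s))
  expect_setequal(pkg_keys_as_labels(cons), oracle_split_keys(tr))
})

test_that("alignment simulation is seeded; rate zero gives constant columns", {
  tr <- simulate_species_tree(6, seed = 11)
  a0 <- simulate_alignment(tr, 25, subst_rate = 0, seed = 12)
  expect_true(all(apply(a0$mat, 2, function(col) length(unique(col)) == 1L)))
  a1 <- simulate_alignment(tr, 25, subst_rate = 1, seed = 13)
  a2 <- simulate_alignment(tr, 25, subst_rate = 1, seed = 13)
  expect_identical(a1$mat, a2$mat)
})

test_that("noise-free scenarios reproduce their truth tables exactly", {
  set.seed(99)
  for (rep in 1:20) {
    n_taxa <- sample(8:14, 1)
    n_events <- sample(0:2, 1)
    disp <- if (n_events) sample(1:3, n_events, replace = TRUE) else integer(0)
    cfg <- scenario_config(
      n_taxa = n_taxa, displacements = disp, n_samples = 8,
      perturb_rate = 0, n_columns_a = 8, n_columns_b = 8, seed = 5000 + rep
    )
    sc <- generate_scenario(cfg)
    calls <- classify_species(
      majority_rule_consensus(split_frequencies(sc$samples_a)),
      majority_rule_consensus(split_frequencies(sc$samples_b))
    )
    flagged <- calls[calls$supported_conflict, ]
    expect_setequal(flagged$unit, sc$truth$species)
    expect_equal(
      flagged$displacement[match(sc$truth$species, flagged$unit)],
      sc$truth$realized_displacement
    )
  }
})

test_that("zero-event scenarios classify everything as congruent", {
  cfg <- scenario_config(
    n_taxa = 10, displacements = integer(0), n_samples = 10,
    perturb_rate = 0, n_columns_a = 8, n_columns_b = 8, seed = 77
  )
  sc <- generate_scenario(cfg)
  expect_equal(nrow(sc$truth), 0L)
  expect_setequal(oracle_split_keys(sc$derived), oracle_split_keys(sc$base))
  calls <- classify_species(
    as_consensus_tree(sc$base, 1), as_consensus_tree(sc$derived, 1)
  )
  expect_true(all(calls$category == "congruent"))
})

test_that("recovery degrades monotonely with perturbation noise", {
  rates <- c(0, 0.1, 0.3)
  recov <- vapply(rates, function(r) {
    hits <- vapply(1:6, function(s) {
      cfg <- scenario_config(
        n_taxa = 10, displacements = c(2L, 3L), n_samples = 100,
        perturb_rate = r, n_columns_a = 8, n_columns_b = 8, seed = 300 + s
      )
      sc <- generate_scenario(cfg)
      score_scenario(sc)$recovery_hyb
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_gte(recov[1] + 0.02, recov[2])
  expect_gte(recov[2] + 0.02, recov[3])
  expect_equal(recov[1], 1)
})

test_that("multi-accession species come out as near-zero-length cherries", {
  cfg <- scenario_config(
    n_taxa = 8, displacements = integer(0), n_samples = 5, perturb_rate = 0,
    accessions_per_species = c(sp02 = 3L), n_columns_a = 8, n_columns_b = 8,
    seed = 123
  )
  sc <- generate_scenario(cfg)
  accs <- paste0("sp02_acc", 1:3)
  expect_true(all(accs %in% sc$base_accessions$tip.label))
  cons <- as_consensus_tree(sc$base_accessions, 1)
  # the accession clade is monophyletic
  expect_true(any(vapply(cons$edges$leaves, function(L) setequal(L, accs),
                         logical(1))))
  map <- sc$taxon_map
  expect_true("sp02" %in% shared_species(map))
})

test_that("scenario directories round-trip through the standard formats", {
  cfg <- scenario_config(
    n_taxa = 9, displacements = 2L, n_samples = 6, perturb_rate = 0,
    n_columns_a = 12, n_columns_b = 12, seed = 55
  )
  sc <- generate_scenario(cfg)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_setequal(
    list.files(dir),
    c("base.nwk", "derived.nwk", "cp_samples.t", "its_samples.t",
      "alignment_A.fasta", "alignment_B.fasta", "taxon_map.tsv",
      "truth.tsv", "config.json")
  )
  back <- read_tree_samples(file.path(dir, "cp_samples.t"), "cpDNA")
  expect_length(back, 6L)
  expect_setequal(back$trees[[1]]$tip.label, sc$derived$tip.label)
  aln <- read_alignment(file.path(dir, "alignment_A.fasta"))
  expect_equal(dim(aln), dim(sc$alignment_a))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(truth$species, sc$truth$species)
})

test_that("a study-scale tree recovers implanted events exactly without noise", {
  cfg <- scenario_config(
    n_taxa = 49, displacements = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    n_samples = 6, perturb_rate = 0, n_columns_a = 8, n_columns_b = 8,
    seed = 17
  )
  sc <- generate_scenario(cfg)
  s <- score_scenario(sc)
  expect_equal(s$recovery_hyb, 1)
  expect_equal(s$recovery_ils, 1)
  expect_equal(s$fpr, 0)
})

test_that("dense paper-scale event sets generate in fast attribution mode", {
  cfg <- scenario_config(n_samples = 10, n_columns_a = 8, n_columns_b = 8,
                         seed = 3)
  expect_equal(cfg$attribution, "fast")
  expect_equal(cfg$n_taxa, 49L)
  expect_length(cfg$displacements, 32L)
  sc <- generate_scenario(cfg)
  expect_equal(nrow(sc$truth), 32L)
  # each event is recorded with a re-measured displacement; at this density
  # many moves are partly or fully explained by co-movers, so small values
  # (including 0) are legal records -- the point of fast mode
  expect_true(all(!is.na(sc$truth$realized_displacement)))
  expect_true(all(sc$truth$realized_displacement >= 0L))
  expect_gte(sum(sc$truth$realized_displacement >= 1L), 5L)
  expect_setequal(
    unique(sc$truth$category),
    intersect(c("congruent", "ILS-candidate", "hybridisation-candidate"),
              sc$truth$category)
  )
})
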