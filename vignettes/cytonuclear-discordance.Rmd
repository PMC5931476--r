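---
title: "Detecting chloroplast capture from posterior tree samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chloroplast capture from posterior tree samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodiscord)
```

## The problem

When the same set of species is sequenced for a maternally inherited
chloroplast marker and a biparentally inherited nuclear marker (typically
nrITS), the two gene trees often disagree. Two biological processes produce
such cytonuclear discordance: **incomplete lineage sorting** (ILS), where
ancestral polymorphism persists through rapid successive speciations, and
**chloroplast capture**, where hybridisation followed by backcrossing fixes
one species' plastid genome in another species. The practical question for a
systematist staring at two conflicting Bayesian consensus trees is: *which
species are discordant, how strongly, and which process is the more
plausible cause for each?*

`cytodiscord` implements a topology-based answer built from four
ingredients:

1. **Consensus summaries** of each genome's post-burn-in posterior tree
   sample (majority-rule, strict, semi-strict).
2. **Internode certainty (IC)** on the pooled two-genome tree population,
   quantifying per-branch conflict between the genomes.
3. A **per-species classification**: species in supported conflict
   (posterior probability above a threshold on both sides) are flagged, their
   topological **node displacement** is measured, and single-node shifts are
   labelled ILS candidates while multi-node shifts are labelled
   hybridisation candidates.
4. A **parsimony ILD permutation test** of overall data-set incongruence.

## Bipartitions and consensus trees

All tree comparison happens on unrooted bipartitions (splits): cutting one
internal edge divides the leaves into two complementary sets. Splits are
canonicalised on the side that excludes the alphabetically first leaf, which
makes equality a string comparison and reduces the compatibility test to
"disjoint or nested".

`split_frequencies()` counts, per tree population, the fraction of trees
containing each split, and pools several populations with weights. The
pooling weights default to 1/2 per genome *regardless of sample counts*:
each analysis contributes equally, exactly as when two equal-length
post-burn-in runs are concatenated. `majority_rule_consensus()` keeps the
splits with pooled frequency strictly above the threshold (default 0.5).
Splits lying exactly at the threshold — which happens systematically when two
genomes of equal weight disagree — are added greedily in descending
frequency, ties broken lexicographically on the canonical key, so output is
deterministic. `strict_consensus()` and `semistrict_consensus()`
(combinable-component) complete the consensus family.

Burn-in is a prefix operation: `apply_burnin()` drops the first
`floor(fraction * N)` trees (default fraction 0.25) and refuses to run
twice, guarding against accidental double discard.

## Internode certainty

For a split $b$ with pooled frequency $f(b)$, let $b'$ be the *most
prevalent* split incompatible with $b$ in the pooled population. With
$p_1 = f(b)/(f(b)+f(b'))$ and $p_2 = 1 - p_1$,

$$\mathrm{IC}(b) = 1 + p_1 \log_2 p_1 + p_2 \log_2 p_2 ,$$

i.e. one minus the two-outcome Shannon entropy of the relative frequencies.
IC is 1 when no conflicting split is observed, and 0 when the strongest
conflicting split is exactly as frequent as $b$. Base-2 logarithms are
essential: a split at 100% in one genome and 50% in the other, contradicted
by the remaining 50%, pools to frequencies 0.75 versus 0.25 and gives
IC $= 1 + 0.75\log_2 0.75 + 0.25\log_2 0.25 = 0.1887$, conventionally
reported as 0.18. Only the single most prevalent conflicting split enters
the formula (not the sum over all conflicting splits); this matches both
worked values above and keeps IC in $[0,1]$.

```{r ic-example}
ab <- parse_newick("((A,B),(C,D),(E,F));")
ac <- parse_newick("((A,C),(B,D),(E,F));")
cp  <- tree_samples(rep(list(ab), 100), "cpDNA")
its <- tree_samples(c(rep(list(ab), 50), rep(list(ac), 50)), "nrITS")
tab <- split_frequencies(list(cp, its))
internode_certainty(tab, c("A", "B"))
```

## Supported conflict and node displacement

A species is *in supported conflict* when the two genome consensus trees
contain incompatible splits, each with support above the threshold (default
PP > 0.95; requiring the threshold on both sides is the stricter of the two
readings and the default, one-sided testing is available via `both_sides =
FALSE`), **and** the incompatibility involves that species — operationally,
restricting both splits to the leaf set without the species makes them
compatible. This restriction test is what distinguishes a species that
moved from a bystander whose neighbourhood was invaded.

Conflicts are attributed to species greedily: `classify_species()`
repeatedly flags the species whose removal resolves the largest number of
outstanding supported conflict pairs, re-evaluating after each removal,
until no remaining pair is resolvable by removing one further species. Ties
are broken towards the species with the larger measured displacement, then
alphabetically; the whole procedure is deterministic.

**Node displacement** operationalises "how many nodes apart are the two
placements". The species is pruned from both trees; its attachment edge in
each pruned tree is identified, and the attachment context from one tree is
matched to the most similar edge of the other (maximum overlap of split
sides, ties resolved towards the nearest edge). The displacement is the
number of edges the attachment point must cross between the matched edge
and the actual attachment edge — a distance in the edge-adjacency graph, so
an NNI-scale shift scores exactly 1. Both directions are measured and the
maximum is reported. Displacement 1 yields `ILS-candidate`, displacement
$\ge 2$ `hybridisation-candidate`; branch lengths are never used in the
category rule (the crossed path length is reported alongside, for
inspection, when the input trees carry lengths).

Species with several accessions are collapsed to one leaf when their
accessions are monophyletic in both consensus trees; otherwise each
accession is classified on its own, which reproduces the situation where
one individual of a species carries a captured plastid while its
conspecifics do not.

### Identifiability

A single-edge regraft is not always attributable to a unique species: when
a leaf moves out of a two-leaf cherry into another two-leaf cherry, the
resulting tree pair is symmetric in up to three leaves, and no topology-only
method can name the mover. The classifier therefore resolves such ties by a
fixed deterministic rule, and the scenario generator (below), in its strict
mode, simply never implants an event whose attribution would be ambiguous.
At very high event densities the problem compounds: events land in each
other's neighbourhoods and joint attribution stops being identifiable at
all. This is a limit of the inference problem, not of the implementation —
it is the formal counterpart of the hedging any empirical study must apply
to per-species capture calls at high discordance.

## The ILD test

The incongruence length difference statistic is
$D = L(A{+}B) - L(A) - L(B)$, where $L$ is the best Fitch parsimony tree
length of a character partition. The null distribution repartitions the
pooled included columns into pseudo-partitions of the original sizes,
without replacement; the p-value uses the $(1+k)/(1+R)$ correction (so
$p \ge 1/(R+1)$; the raw proportion is also reported, since with $R = 100$
replicates the smallest corrected p is $\approx 0.0099$ while the raw
proportion can reach 0).

Fitch lengths treat IUPAC ambiguity codes as state sets and gaps as missing
data (not a fifth state). For nine or fewer taxa the search is exact —
exhaustive over all unrooted topologies — and the per-column Fitch scores of
every topology are cached across permutation replicates, which makes the
whole permutation test essentially free: each replicate is a pair of
column-subset row-sums and a minimum. Above nine taxa the search falls back
to random stepwise addition with NNI or SPR swapping to a local optimum
(ten random-addition starts and at most 100 retained equally best trees by
default). NNI/SPR is used rather than TBR: at the instance sizes where the
heuristic path is taken the difference is marginal, the statistic depends
only on best lengths, and the settings record in every result documents the
search actually used.

## The synthetic-data generator

Because the real study inputs are GenBank sequences and MCMC runs, testing
uses fully specified synthetic worlds:

* `simulate_species_tree()` draws a pure-birth (Yule) tree — every extant
  lineage equally likely to split — with exponential waiting times, via
  `ape::rphylo(birth = 1, death = 0)`.
* `inject_capture()` prunes one species and regrafts it onto an edge at a
  *chosen* displacement, verified by the same `node_displacement()` the
  classifier uses. This models chloroplast capture as a topology-only event,
  which is the right level of abstraction for a topology-only classifier.
* `emulate_posterior()` stands in for an MCMC sample: each drawn tree
  applies, independently per internal edge with probability $p$, a uniform
  re-resolution among the edge's three NNI configurations. An NNI at an edge
  destroys that edge's split in 2 of the 3 resolutions and touches no other
  split, so the expected support of a true edge is exactly
  $1 - \tfrac{2}{3}p$ — an analytically predictable noise model, which real
  MCMC output does not offer. What this emulation does **not** model:
  correlated uncertainty along the tree, branch-length posteriors, or the
  low-frequency long-range topologies a real posterior contains. Passing
  recovery tests under this model therefore demonstrates the pipeline's
  contracts (consensus, IC, conflict attribution), not field performance on
  any particular empirical data set.
* `simulate_alignment()` evolves Jukes-Cantor sequences on a tree
  (`phangorn::simSeq`), for calibrating the ILD test under a true null
  (both partitions on one tree) and under forced conflict.
* `generate_scenario()` bundles everything with a truth table. Default
  conditions mirror the study system this package was built around: 49
  species, ten single-node events and twenty-two deeper events, 500
  posterior samples per genome, 5% per-edge perturbation, ITS-length (853)
  and plastid-length (6764) alignments. Dense event sets of that kind are
  generated in `"fast"` attribution mode (each event's own displacement is
  verified); smaller event sets default to `"strict"` mode, where placements
  are rejection-sampled until the classifier provably recovers the full
  truth table from the noise-free trees — the mode used by all exactness
  tests.

```{r scenario, eval = FALSE}
sc <- generate_scenario(scenario_config(
  n_taxa = 12, displacements = c(1L, 3L),
  n_samples = 500, perturb_rate = 0.05, seed = 1
))
cons_a <- majority_rule_consensus(split_frequencies(sc$samples_a))
cons_b <- majority_rule_consensus(split_frequencies(sc$samples_b))
classify_species(cons_a, cons_b)
```

## Numerical and design choices

* Consensus inclusion uses strictly-greater-than the threshold, with greedy
  completion only for exact ties; frequency comparisons use an absolute
  tolerance of $10^{-12}$ (pooled frequencies are sums of two rationals and
  can land exactly on 0.5 only up to floating point).
* Trees are treated as unrooted throughout the split machinery even when
  written rooted; MCMC rooting is arbitrary and IC/consensus are
  split-level quantities.
* Support annotations are accepted in internal-node-label position or as
  the first numeric value in a comment attached to the node; the node label
  wins if both are present.
* Leaf labels are matched case-sensitively after stripping quotes and
  surrounding whitespace.
* Polytomies are resolved deterministically (input order) before Fitch
  scoring; consensus trees may contain polytomies and all classifier code
  handles them.
* All randomness flows from explicit seeds; every pipeline stage derives
  its own stream from the one master seed, so a report bundle is a pure
  function of (inputs, config, seed) and reruns are byte-identical.

The test suite exercises the consensus machinery against brute-force
split-counting oracles on exhaustive 5- and 6-leaf topology sets, the Fitch
implementation against the exhaustive minimum over internal state
assignments on every binary topology of up to 7 leaves, the ILD test
against an exhaustive-repartition oracle on a tiny instance and against its
nominal rejection rate under a simulated null (200 simulations, 100
replicates each), and capture recovery on noise-free scenarios (exact, 100
random configurations) and noisy ones (5% perturbation, 500 trees per
genome, 100 replicates; twelve-taxon scenarios with implanted displacements
of 2 and 3). Those problem sizes are the package's calibration conditions;
larger worlds are supported but not routinely simulated.

## Known limitations

* The classifier is topology-only; it cannot use the "short branch
  lengths" heuristic sometimes invoked to argue for ILS, beyond reporting
  path lengths.
* IC uses the single most prevalent conflicting split; IC-All and
  tree-certainty sums are out of scope, as are clade-credibility (MCC)
  summaries — the consensus family here is MRC/strict/semi-strict.
* The ILD permutation test inherits the known behaviour of the statistic
  itself: it tests exchangeability of columns across partitions, which is a
  proxy for topological incongruence, not a direct test of it.
* Which genome is "captured" is a labelling decision for the user: the
  classifier detects and grades discordance per species; deciding that the
  plastid is the intruder (chloroplast capture) versus the nuclear copy
  (nrDNA capture) requires external evidence, exactly as in the empirical
  literature.
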