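#' Build an accession-to-species map for two genomes
#'
#' @param mapping a data frame (or path to a TSV) with columns `accession`,
#'   `species`, `genome`.
#' @param labels_a,labels_b optional leaf label sets of the two genomes'
#'   trees; when given, rows referencing unknown labels are dropped with a
#'   warning and unmapped labels are reported.
#' @param genome_a,genome_b the `genome` values identifying the two sources
#'   (defaults: the first two distinct values, in order of appearance).
#' @return a `taxon_map`: a tibble of the (deduplicated) rows, with the
#'   shared-species set in `attr(, "shared")` and per-genome species sets in
#'   `attr(, "species_a")` / `attr(, "species_b")`.
#' @export
build_taxon_map <- function(mapping, labels_a = NULL, labels_b = NULL,
                            genome_a = NULL, genome_b = NULL) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- readr::read_tsv(mapping, show_col_types = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("accession", "species", "genome") %in% names(mapping)))
  if (anyDuplicated(mapping)) {
    warning("duplicate mapping rows removed")
    mapping <- dplyr::distinct(mapping)
  }
  multi <- dplyr::summarise(
    dplyr::group_by(mapping, .data$accession),
    n_species = dplyr::n_distinct(.data$species), .groups = "drop"
  )
  if (any(multi$n_species > 1L)) {
    stop(
      "accession(s) mapped to more than one species: ",
      paste(multi$accession[multi$n_species > 1L], collapse = ", ")
    )
  }
  genomes <- unique(mapping$genome)
  if (is.null(genome_a)) genome_a <- genomes[1]
  if (is.null(genome_b)) genome_b <- setdiff(genomes, genome_a)[1]
  check_labels <- function(rows, labels, tag) {
    if (is.null(labels)) return(rows)
    bad <- setdiff(rows$accession, labels)
    if (length(bad)) {
      warning(
        "dropping ", tag, " accession(s) absent from the tree: ",
        paste(bad, collapse = ", ")
      )
      rows <- rows[!rows$accession %in% bad, , drop = FALSE]
    }
    unmapped <- setdiff(labels, rows$accession)
    attr(rows, "unmapped") <- unmapped
    rows
  }
  rows_a <- check_labels(mapping[mapping$genome == genome_a, ], labels_a, genome_a)
  rows_b <- check_labels(mapping[mapping$genome == genome_b, ], labels_b, genome_b)
  out <- dplyr::bind_rows(rows_a, rows_b)
  attr(out, "genomes") <- c(genome_a, genome_b)
  attr(out, "species_a") <- unique(rows_a$species)
  attr(out, "species_b") <- unique(rows_b$species)
  attr(out, "shared") <- intersect(unique(rows_a$species), unique(rows_b$species))
  attr(out, "unmapped_a") <- attr(rows_a, "unmapped")
  attr(out, "unmapped_b") <- attr(rows_b, "unmapped")
  class(out) <- c("taxon_map", class(out))
  out
}

#' Species shared by both genomes
#' @param map a `taxon_map`.
#' @export
shared_species <- function(map) attr(map, "shared")

#' Accessions of one species in one genome
#' @keywords internal
species_accessions <- function(map, species, genome) {
  map$accession[map$species == species & map$genome == genome]
}

#' Prune a tree to a leaf subset
#'
#' Induced subtree: unary nodes are suppressed and branch lengths summed
#' across suppressed nodes (via [ape::keep.tip()]).
#'
#' @param tree a `phylo`.
#' @param keep leaf labels to retain (at least 3).
#' @export
prune_to_shared <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 3L) stop("need at least 3 leaves to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}
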