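#' Multiple sequence alignment container
#'
#' A character matrix (taxa x columns, IUPAC nucleotide codes, `-`/`?`/`N`
#' treated as missing) plus a per-column inclusion flag. Original 1-based
#' column coordinates are kept so that exclusion ranges can be reported in
#' the coordinates of the source alignment.
#'
#' @param mat character matrix with taxon row names.
#' @return object of class `dna_alignment`.
#' @export
alignment <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxa: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  mat <- toupper(mat)
  structure(
    list(
      taxa = rownames(mat),
      mat = mat,
      included = rep(TRUE, ncol(mat)),
      coords = seq_len(ncol(mat))
    ),
    class = "dna_alignment"
  )
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(
    "<dna_alignment> ", length(x$taxa), " taxa x ", ncol(x$mat),
    " columns (", sum(x$included), " included)\n", sep = ""
  )
  invisible(x)
}

#' @export
dim.dna_alignment <- function(x) dim(x$mat)

included_matrix <- function(aln) aln$mat[, aln$included, drop = FALSE]

#' Read an alignment from FASTA or NEXUS
#'
#' @param input a file path, or the file content as a single string /
#'   character vector of lines.
#' @param format `"fasta"` or `"nexus"`; guessed from the content when
#'   missing. NEXUS `data`/`characters` blocks, sequential or interleaved,
#'   are supported via [ape::read.nexus.data()].
#' @return a [alignment()] object with all columns included.
#' @export
read_alignment <- function(input, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  is_path <- length(input) == 1L && !grepl("\n", input) && file.exists(input)
  lines <- if (is_path) readLines(input, warn = FALSE) else
    unlist(strsplit(input, "\n", fixed = TRUE))
  if (format == "auto") {
    format <- if (length(lines) && grepl("^\\s*#NEXUS", lines[1], ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "nexus") {
    tmp <- tempfile(fileext = ".nex")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines, tmp)
    seqs <- ape::read.nexus.data(tmp)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
    }
    mat <- do.call(rbind, lapply(seqs, toupper))
    rownames(mat) <- names(seqs)
    return(alignment(mat))
  }
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no FASTA headers found")
  taxa <- sub("^>\\s*", "", lines[headers])
  taxa <- sub("\\s.*$", "", taxa)
  bounds <- c(headers, length(lines) + 1L)
  seqs <- lapply(seq_along(headers), function(i) {
    body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    strsplit(toupper(paste(body, collapse = "")), "", fixed = TRUE)[[1]]
  })
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- taxa
  alignment(mat)
}

#' Write an alignment to FASTA (included columns flagged, all columns kept)
#' @param aln a [alignment()].
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    writeLines(paste(aln$mat[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Exclude alignment columns by 1-based inclusive ranges
#'
#' Excluded columns never contribute to parsimony lengths or informative-site
#' counts; the original coordinates are retained for reporting.
#'
#' @param aln a [alignment()].
#' @param ranges a list of `c(start, end)` pairs, a 2-column matrix, or a
#'   string like `"494-548, 1-10"`.
#' @export
apply_exclusion_ranges <- function(aln, ranges) {
  stopifnot(inherits(aln, "dna_alignment"))
  ranges <- parse_ranges(ranges)
  L <- length(aln$coords)
  for (r in ranges) {
    if (r[1] > r[2]) stop("inverted interval: ", r[1], "-", r[2])
    if (r[1] < 1 || r[2] > max(aln$coords)) {
      stop("interval ", r[1], "-", r[2], " outside alignment coordinates")
    }
    aln$included[aln$coords >= r[1] & aln$coords <= r[2]] <- FALSE
  }
  aln
}

parse_ranges <- function(ranges) {
  if (is.character(ranges)) {
    stopifnot(length(ranges) == 1L)
    parts <- trimws(strsplit(ranges, ",", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    ranges <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", p))[[1]]
      if (length(m) != 3L) stop("cannot parse range: '", p, "'")
      as.integer(m[2:3])
    })
  } else if (is.matrix(ranges)) {
    ranges <- lapply(seq_len(nrow(ranges)), function(i) as.integer(ranges[i, ]))
  } else if (is.numeric(ranges) && length(ranges) == 2L) {
    ranges <- list(as.integer(ranges))
  }
  ranges
}

# IUPAC nucleotide codes as bit sets over (A, C, G, T)
iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L, "-" = 15L, "?" = 15L, X = 15L
)

encode_states <- function(mat) {
  enc <- iupac_bits[mat]
  enc[is.na(enc)] <- 15L
  dim(enc) <- dim(mat)
  rownames(enc) <- rownames(mat)
  enc
}

#' Count parsimony-informative columns
#'
#' A column is parsimony-informative iff at least two distinct unambiguous
#' states each occur in at least two taxa; gaps and ambiguity codes do not
#' count as states. Only included columns are examined.
#'
#' @param aln a [alignment()].
#' @return list with `total` (included column count) and `informative`.
#' @export
count_parsimony_informative <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  m <- included_matrix(aln)
  informative <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
  }
  list(total = ncol(m), informative = informative)
}
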