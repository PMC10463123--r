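# Reference sequence input and in-silico PCR.

#' Read reference sequences from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) of candidate host-plant
#' barcode sequences. The header token before the first whitespace becomes
#' the species id; the remainder is kept as a description. Sequences are
#' uppercased and validated against the IUPAC nucleotide alphabet.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `ref_seqs`: a named character vector of
#'   sequences (names are species ids) with a `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate species id in FASTA: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  residues <- toupper(as.character(set))
  for (i in seq_along(residues)) {
    if (nchar(residues[i]) == 0L) {
      stop("empty sequence for record '", ids[i], "'", call. = FALSE)
    }
    seq_to_masks(residues[i], label = sprintf("record '%s'", ids[i]))
  }
  ref_seqs(stats::setNames(residues, ids), descriptions = desc)
}

#' Construct a reference sequence collection
#'
#' @param sequences Named character vector: species id -> IUPAC nucleotide
#'   string.
#' @param descriptions Optional character vector of free-text descriptions.
#' @return An object of class `ref_seqs`.
#' @export
ref_seqs <- function(sequences, descriptions = NULL) {
  if (length(sequences) == 0L) stop("no sequences given", call. = FALSE)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("every sequence needs a species id (names attribute)", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate species id: ",
         names(sequences)[duplicated(names(sequences))][1L], call. = FALSE)
  }
  sequences <- toupper(sequences)
  for (i in seq_along(sequences)) {
    seq_to_masks(sequences[i], label = sprintf("record '%s'", names(sequences)[i]))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sequences))
  structure(sequences, descriptions = descriptions, class = "ref_seqs")
}

#' @export
print.ref_seqs <- function(x, ...) {
  cat(sprintf("<ref_seqs> %d sequence(s), lengths %d-%d bp\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (or `ref_seqs`) of sequences.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(sequences))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a PCR primer pair
#'
#' Both primers are given 5'->3' as on the order sheet; the reverse primer
#' anneals to the plus strand as its reverse complement.
#'
#' @param forward,reverse IUPAC nucleotide strings, length >= 10.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  for (p in c(forward = forward, reverse = reverse)) {
    if (nchar(p) < 10L) {
      stop("primers must be at least 10 nt long", call. = FALSE)
    }
    seq_to_masks(p, label = "primer")
  }
  structure(list(forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' The ITS2 primer pair used for plant host identification
#'
#' ITS2F (ATGCGATACTTGGTGTGAAT) and ITS3R (GACGCTTCTCCAGACTACAAT), a standard
#' pair amplifying the plant ITS2 region (products around 400-600 bp).
#'
#' @return A `primer_pair`.
#' @export
its_primers <- function() {
  primer_pair(forward = "ATGCGATACTTGGTGTGAAT",
              reverse = "GACGCTTCTCCAGACTACAAT")
}

#' Find primer annealing sites on a template
#'
#' Scans the template for exact-length, zero-mismatch matches of the primer,
#' where a position matches when the primer base and template base are
#' IUPAC-compatible (their base sets intersect). In `forward` orientation the
#' primer is matched as given; in `reverse` orientation its reverse
#' complement is matched, i.e. the position where the reverse primer would
#' anneal to the minus strand.
#'
#' @param template IUPAC nucleotide string.
#' @param primer IUPAC nucleotide string.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Integer vector of 0-based match start positions, ascending
#'   (empty when the primer does not occur).
#' @export
#' @examples
#' find_primer_sites("AAATGCAAA", "ATGC", "forward")  # 2
#' find_primer_sites("AAGCATAA", "ATGC", "reverse")   # 2
find_primer_sites <- function(template,
                              primer,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  query <- if (orientation == "forward") primer else reverse_complement(primer)
  tm <- seq_to_masks(template, label = "template")
  qm <- seq_to_masks(query, label = "primer")
  if (length(qm) > length(tm)) {
    stop("primer is longer than the template", call. = FALSE)
  }
  scan_compatible(tm, qm)
}

#' Extract the in-silico PCR amplicon delimited by a primer pair
#'
#' Requires exactly one forward site and exactly one reverse site downstream
#' of it. The amplicon spans from the first base of the forward primer match
#' through the last base of the reverse primer's annealing site, inclusive,
#' so both primer-binding regions are part of the product -- matching what is
#' sized on a gel. Template bases (including degenerate codes) are retained
#' verbatim.
#'
#' @param template A single sequence: either a 1-element named character
#'   vector, an element of a `ref_seqs`, or a plain string plus `species_id`.
#' @param primers A `primer_pair`.
#' @param species_id Label for the amplicon; defaults to `names(template)`.
#' @return An object of class `amplicon`: list with `species_id`, `residues`,
#'   `length`, and the 0-based half-open template interval `start`, `end`.
#' @export
extract_amplicon <- function(template, primers, species_id = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  if (is.null(species_id)) {
    species_id <- if (!is.null(names(template))) names(template)[1L] else "?"
  }
  residues <- toupper(as.character(template)[1L])

  fwd <- find_primer_sites(residues, primers$forward, "forward")
  if (length(fwd) == 0L) {
    stop("no forward primer site in template '", species_id, "'",
         call. = FALSE)
  }
  if (length(fwd) > 1L) {
    stop("ambiguous priming: ", length(fwd),
         " forward primer sites in template '", species_id, "'",
         call. = FALSE)
  }
  rev_sites <- find_primer_sites(residues, primers$reverse, "reverse")
  rev_sites <- rev_sites[rev_sites >= fwd + nchar(primers$forward)]
  if (length(rev_sites) == 0L) {
    stop("no reverse primer site downstream of the forward site in template '",
         species_id, "'", call. = FALSE)
  }
  if (length(rev_sites) > 1L) {
    stop("ambiguous priming: ", length(rev_sites),
         " reverse primer sites in template '", species_id, "'",
         call. = FALSE)
  }
  start <- fwd
  end <- rev_sites + nchar(primers$reverse)  # half-open [start, end)
  structure(
    list(species_id = species_id,
         residues = substr(residues, start + 1L, end),
         length = end - start,
         start = start,
         end = end),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s: %d bp (template interval [%d, %d))\n",
              x$species_id, x$length, x$start, x$end))
  invisible(x)
}

#' Extract amplicons for every sequence in a collection
#'
#' @param sequences A `ref_seqs` (or named character vector).
#' @param primers A `primer_pair`.
#' @return Named list of `amplicon` objects, one per input sequence.
#'   Extraction failures are propagated with the species named.
#' @export
extract_amplicons <- function(sequences, primers) {
  ids <- names(sequences)
  out <- lapply(seq_along(sequences), function(i) {
    extract_amplicon(unclass(sequences)[i], primers, species_id = ids[i])
  })
  stats::setNames(out, ids)
}
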