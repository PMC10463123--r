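# IUPAC nucleotide alphabet utilities.
#
# Bases are encoded as 4-bit masks (A=1, C=2, G=4, T=8); a degenerate code is
# the OR of the bases it stands for. Two codes are "compatible" when their
# masks intersect, which is the matching rule used for both primer annealing
# and restriction-site recognition throughout the package.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC nucleotide codes accepted by the package
#'
#' @return Character vector of the 15 valid single-letter codes.
#' @export
iupac_alphabet <- function() names(IUPAC_MASK)

## Split a sequence string into its IUPAC bitmasks; errors with position on
## any invalid character. `label` names the offending record in messages.
seq_to_masks <- function(residues, label = "sequence") {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  masks <- IUPAC_MASK[chars]
  bad <- which(is.na(masks))
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' in %s at position %d",
                 chars[bad[1L]], label, bad[1L]), call. = FALSE)
  }
  unname(masks)
}

## TRUE when the string contains only A/C/G/T (no degenerate codes).
is_unambiguous <- function(residues) {
  !grepl("[^ACGT]", toupper(residues))
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes are complemented onto their IUPAC partners (R<->Y,
#' K<->M, B<->V, D<->H; S, W and N are self-complementary).
#'
#' @param residues A nucleotide string over the IUPAC alphabet.
#' @return The reverse-complemented string, uppercase.
#' @export
#' @examples
#' reverse_complement("ATGC")   # "GCAT"
#' reverse_complement("ARN")    # "NYT"
reverse_complement <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("invalid nucleotide in sequence: ",
         chars[which(is.na(comp))[1L]], call. = FALSE)
  }
  paste(rev(unname(comp)), collapse = "")
}

## Scan `template_masks` for windows where every position is IUPAC-compatible
## with `query_masks`. Returns 0-based start positions, ascending.
## Vectorised over template positions: O(n * m) with m = query length.
scan_compatible <- function(template_masks, query_masks) {
  n <- length(template_masks)
  m <- length(query_masks)
  if (m > n) return(integer(0))
  hits <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    hits <- hits &
      bitwAnd(template_masks[j:(n - m + j)], query_masks[j]) > 0L
  }
  which(hits) - 1L
}
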