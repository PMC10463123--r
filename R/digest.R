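# Virtual restriction digestion and the per-community reference database.

#' Find restriction enzyme recognition sites
#'
#' Scans a single strand for positions where every base of the recognition
#' sequence is IUPAC-compatible with the template (a degenerate template base
#' such as N matches any recognition base). Overlapping occurrences are all
#' reported. The built-in enzymes have palindromic sites, so the reverse
#' strand contributes no additional cuts.
#'
#' @param residues IUPAC nucleotide string (an amplicon's residues).
#' @param enzyme A `restriction_enzyme`.
#' @return Integer vector of 0-based site start positions, ascending.
#' @export
#' @examples
#' taqi <- builtin_enzymes()$TaqI
#' find_recognition_sites("TCGATCGA", taqi)  # 0 4
find_recognition_sites <- function(residues, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (nchar(residues) == 0L) stop("empty sequence", call. = FALSE)
  tm <- seq_to_masks(residues, label = "sequence")
  qm <- seq_to_masks(enzyme$recognition, label = "recognition site")
  if (length(qm) > length(tm)) return(integer(0))
  scan_compatible(tm, qm)
}

#' Virtually digest an amplicon with one restriction enzyme
#'
#' Cut positions are `site start + cut_offset` for every recognition site;
#' fragment lengths are the gaps between consecutive cut positions including
#' both ends of the molecule. A cut falling exactly at position 0 or at the
#' amplicon end would create a zero-length fragment; such fragments are
#' dropped (with a message). Duplicate cut positions arising from
#' overlapping sites are counted once.
#'
#' @param amplicon An `amplicon`, or a plain nucleotide string.
#' @param enzyme A `restriction_enzyme`.
#' @return Integer vector of fragment lengths in bases, descending. With no
#'   recognition site the single uncut length is returned.
#' @export
#' @examples
#' digest_fragments("AAATCGAAAA", builtin_enzymes()$TaqI)  # 6 4
digest_fragments <- function(amplicon, enzyme) {
  residues <- if (inherits(amplicon, "amplicon")) amplicon$residues
              else toupper(as.character(amplicon)[1L])
  len <- nchar(residues)
  if (len < 1L) stop("amplicon must have length >= 1", call. = FALSE)
  sites <- find_recognition_sites(residues, enzyme)
  cuts <- unique(sites + enzyme$cut_offset)
  boundary_cuts <- cuts[cuts <= 0L | cuts >= len]
  if (length(boundary_cuts) > 0L) {
    message(sprintf(
      "%s cut at molecule boundary (position %s): zero-length fragment dropped",
      enzyme$name, paste(boundary_cuts, collapse = ", ")))
    cuts <- cuts[cuts > 0L & cuts < len]
  }
  frags <- diff(c(0L, sort(cuts), len))
  sort(as.integer(frags), decreasing = TRUE)
}

#' Build a species' fragment-length profile over an enzyme panel
#'
#' Each enzyme digests the amplicon independently (three separate reactions,
#' not a sequential double digest). Sites overlapping a degenerate template
#' base are uncertain cuts; their count per enzyme is recorded in the
#' `degenerate_sites` attribute so callers can flag or exclude them.
#'
#' @param amplicon An `amplicon`.
#' @param panel List of `restriction_enzyme` objects (or built-in names).
#' @return An object of class `fragment_profile`: list with `species_id`,
#'   `amplicon_length` and `fragments`, a named list mapping enzyme name to
#'   a descending integer vector of fragment lengths.
#' @export
build_profile <- function(amplicon, panel) {
  stopifnot(inherits(amplicon, "amplicon"))
  panel <- resolve_panel(panel)
  degen <- integer(length(panel))
  frags <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    enz <- panel[[i]]
    frags[[i]] <- digest_fragments(amplicon, enz)
    if (!is_unambiguous(amplicon$residues)) {
      degen[i] <- count_degenerate_sites(amplicon$residues, enz)
    }
  }
  structure(
    list(species_id = amplicon$species_id,
         amplicon_length = amplicon$length,
         fragments = stats::setNames(frags, names(panel))),
    degenerate_sites = stats::setNames(degen, names(panel)),
    class = "fragment_profile"
  )
}

## Number of recognition sites whose template window contains a degenerate
## base (an uncertain cut).
count_degenerate_sites <- function(residues, enzyme) {
  sites <- find_recognition_sites(residues, enzyme)
  if (length(sites) == 0L) return(0L)
  m <- nchar(enzyme$recognition)
  sum(vapply(sites, function(s) {
    !is_unambiguous(substr(residues, s + 1L, s + m))
  }, TRUE))
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s (amplicon %d bp)\n",
              x$species_id, x$amplicon_length))
  for (enz in names(x$fragments)) {
    cat(sprintf("  %-8s %s\n", enz, paste(x$fragments[[enz]], collapse = " ")))
  }
  invisible(x)
}

#' Build the reference database of virtual digests for one community
#'
#' Extracts the amplicon for every community member and digests it with the
#' panel. Communities larger than 8 species trigger a warning (the method is
#' designed for small communities of known membership) but are processed.
#'
#' @param sequences A `ref_seqs` collection covering the community.
#' @param community Character vector of species ids in the community.
#' @param primers A `primer_pair` (default [its_primers()]).
#' @param panel List of `restriction_enzyme` objects or built-in names
#'   (default all three built-ins).
#' @param community_id Label for the community.
#' @return An object of class `reference_db`: list with `community_id`,
#'   `panel` (enzyme names), `enzymes` and `profiles` (species id ->
#'   `fragment_profile`).
#' @export
build_reference_db <- function(sequences, community,
                               primers = its_primers(),
                               panel = builtin_enzymes(),
                               community_id = "community") {
  panel <- resolve_panel(panel)
  missing <- setdiff(community, names(sequences))
  if (length(missing) > 0L) {
    stop("no reference sequence for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(community) > 8L) {
    warning("community '", community_id, "' has ", length(community),
            " species (> 8); discrimination may be unreliable",
            call. = FALSE)
  }
  profiles <- lapply(community, function(sp) {
    amp <- extract_amplicon(unclass(sequences)[sp], primers, species_id = sp)
    build_profile(amp, panel)
  })
  structure(
    list(community_id = community_id,
         panel = names(panel),
         enzymes = panel,
         profiles = stats::setNames(profiles, community)),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %s: %d species, panel {%s}\n",
              x$community_id, length(x$profiles),
              paste(x$panel, collapse = ", ")))
  invisible(x)
}

#' Export a reference database as a long-format data frame
#'
#' @param db A `reference_db`.
#' @return Data frame with columns `species_id`, `enzyme`, `fragment_index`,
#'   `length_bp`.
#' @export
db_to_table <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  rows <- list()
  for (sp in names(db$profiles)) {
    prof <- db$profiles[[sp]]
    for (enz in names(prof$fragments)) {
      fr <- prof$fragments[[enz]]
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, enzyme = enz,
        fragment_index = seq_along(fr), length_bp = fr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
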