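# Enzyme-panel design: can a gel tell the community members apart, and what
# is the smallest panel that does?

#' Are two fragment profiles distinguishable on a gel?
#'
#' Two profiles are distinguishable when, for at least one enzyme in the
#' panel, their visible band lists differ. Band lists are "the same" when
#' they have equal length and each positional pair (after descending sort)
#' comigrates under the gel model.
#'
#' @param a,b `fragment_profile` objects covering the same enzyme panel.
#' @param gel A `gel_model`.
#' @param enzymes Optional subset of enzyme names to compare (defaults to
#'   the full shared panel).
#' @return `TRUE` if some enzyme separates the two species.
#' @export
profiles_distinguishable <- function(a, b, gel = gel_model(),
                                     enzymes = NULL) {
  stopifnot(inherits(a, "fragment_profile"), inherits(b, "fragment_profile"))
  if (is.null(enzymes)) {
    enzymes <- names(a$fragments)
    if (!setequal(enzymes, names(b$fragments))) {
      stop("profiles cover different enzyme panels", call. = FALSE)
    }
  } else {
    missing <- setdiff(enzymes, intersect(names(a$fragments),
                                          names(b$fragments)))
    if (length(missing) > 0L) {
      stop("enzyme not present in both profiles: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (enz in enzymes) {
    if (!bands_same(visible_bands(a$fragments[[enz]], gel),
                    visible_bands(b$fragments[[enz]], gel), gel)) {
      return(TRUE)
    }
  }
  FALSE
}

## Positional band-list equality under comigration.
bands_same <- function(x, y, gel) {
  if (length(x) != length(y)) return(FALSE)
  if (length(x) == 0L) return(TRUE)
  all(comigrates(x, y, gel))
}

#' Select a minimal enzyme panel discriminating a community
#'
#' Exhaustively searches enzyme subsets of size `1..max_enzymes`, ordered by
#' subset size then lexicographically by enzyme name, and returns the first
#' subset under which every pair of community members is distinguishable. If
#' no subset fully discriminates, the subset maximising the number of
#' distinguishable pairs (ties broken by the same ordering) is returned
#' together with the residual indistinguishable pairs. The fixed ordering
#' makes the result deterministic.
#'
#' @param db A `reference_db` whose profiles cover every candidate enzyme.
#' @param gel A `gel_model`.
#' @param max_enzymes Largest panel size to consider (default 3, the number
#'   of digestion reactions run per sample in practice).
#' @return An object of class `panel_report`: list with `panel`,
#'   `complete` (all pairs distinguished?), `distinguishable_pairs`,
#'   `total_pairs` and `indistinguishable` (list of species-id pairs).
#' @export
select_panel <- function(db, gel = gel_model(), max_enzymes = 3L) {
  stopifnot(inherits(db, "reference_db"))
  candidates <- sort(db$panel)
  species <- names(db$profiles)
  pairs <- if (length(species) >= 2L) utils::combn(sort(species), 2L)
           else matrix(character(0), nrow = 2L)
  total_pairs <- ncol(pairs)

  score <- function(subset) {
    ok <- logical(total_pairs)
    for (k in seq_len(total_pairs)) {
      ok[k] <- profiles_distinguishable(db$profiles[[pairs[1L, k]]],
                                        db$profiles[[pairs[2L, k]]],
                                        gel, enzymes = subset)
    }
    ok
  }

  best <- NULL
  for (size in seq_len(min(max_enzymes, length(candidates)))) {
    subsets <- utils::combn(candidates, size, simplify = FALSE)
    for (subset in subsets) {
      ok <- score(subset)
      if (all(ok)) {
        return(panel_report(subset, ok, pairs))
      }
      if (is.null(best) || sum(ok) > best$n_ok) {
        best <- list(subset = subset, ok = ok, n_ok = sum(ok))
      }
    }
  }
  if (is.null(best)) {  # single species: nothing to distinguish
    return(panel_report(candidates[seq_len(min(1L, length(candidates)))],
                        logical(0), pairs))
  }
  panel_report(best$subset, best$ok, pairs)
}

panel_report <- function(panel, ok, pairs) {
  indist <- lapply(which(!ok), function(k) pairs[, k])
  structure(
    list(panel = panel,
         complete = all(ok),
         distinguishable_pairs = sum(ok),
         total_pairs = length(ok),
         indistinguishable = indist),
    class = "panel_report"
  )
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("<panel_report> {%s}: %d/%d pairs distinguishable%s\n",
              paste(x$panel, collapse = ", "),
              x$distinguishable_pairs, x$total_pairs,
              if (x$complete) " (complete)" else ""))
  for (p in x$indistinguishable) {
    cat("  indistinguishable: ", p[1L], " ~ ", p[2L], "\n", sep = "")
  }
  invisible(x)
}

#' Count distinguishable species pairs under a given enzyme subset
#'
#' @param db A `reference_db`.
#' @param enzymes Character vector of enzyme names (subset of `db$panel`).
#' @param gel A `gel_model`.
#' @return Integer count of distinguishable pairs.
#' @export
count_distinguishable_pairs <- function(db, enzymes, gel = gel_model()) {
  species <- sort(names(db$profiles))
  if (length(species) < 2L) return(0L)
  pairs <- utils::combn(species, 2L)
  sum(vapply(seq_len(ncol(pairs)), function(k) {
    profiles_distinguishable(db$profiles[[pairs[1L, k]]],
                             db$profiles[[pairs[2L, k]]],
                             gel, enzymes = enzymes)
  }, TRUE))
}
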