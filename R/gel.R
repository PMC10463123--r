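# Gel detection model: sizing window, relative tolerance, comigration.

#' Define a gel detection model
#'
#' Encapsulates what an agarose gel can resolve: a detection window given by
#' the ladder (default 25-766 bp) and a relative sizing tolerance. Two bands
#' of size `a` and `b` comigrate (are indistinguishable) when
#' `|a - b| <= rel_tol * max(a, b)`. The 5% default is a conventional
#' agarose sizing accuracy and is a parameter, not a constant.
#'
#' @param min_size,max_size Detection window bounds in bases.
#' @param rel_tol Dimensionless relative sizing tolerance in `[0, 1)`.
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(min_size = 25, max_size = 766, rel_tol = 0.05) {
  if (!(min_size > 0 && min_size < max_size)) {
    stop("need 0 < min_size < max_size", call. = FALSE)
  }
  if (rel_tol < 0 || rel_tol >= 1) {
    stop("rel_tol must be in [0, 1)", call. = FALSE)
  }
  structure(list(min_size = min_size, max_size = max_size,
                 rel_tol = rel_tol),
            class = "gel_model")
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf("<gel_model> window [%g, %g] bp, rel_tol %g\n",
              x$min_size, x$max_size, x$rel_tol))
  invisible(x)
}

#' Do two band sizes comigrate under a gel model?
#'
#' @param a,b Band sizes in bases (vectorised).
#' @param gel A `gel_model`.
#' @return Logical vector.
#' @export
comigrates <- function(a, b, gel) {
  abs(a - b) <= gel$rel_tol * pmax(a, b)
}

#' Bands visible on a gel for a set of fragment lengths
#'
#' Drops fragments outside the detection window, then merges comigrating
#' fragments into single bands: fragments are walked in descending size
#' order, and a fragment joins the current band if it comigrates with every
#' fragment already in it (complete linkage; deterministic). With
#' `transitive = TRUE` a fragment joins if it comigrates with the previous
#' fragment alone (single linkage), a variant useful for sensitivity
#' analysis. Each band's apparent size is the mean of its members, rounded
#' to the nearest base.
#'
#' @param fragments Numeric vector of fragment lengths.
#' @param gel A `gel_model`.
#' @param transitive Use single-linkage (chain) merging instead of the
#'   default complete-linkage rule.
#' @return Integer vector of band sizes, descending. May be empty when no
#'   fragment falls in the window (an invisible digest).
#' @export
#' @examples
#' visible_bands(c(500, 20), gel_model())        # 500
#' visible_bands(c(104, 100), gel_model())       # 102
visible_bands <- function(fragments, gel = gel_model(), transitive = FALSE) {
  if (length(fragments) == 0L) stop("no fragments given", call. = FALSE)
  keep <- fragments >= gel$min_size & fragments <= gel$max_size
  fr <- sort(fragments[keep], decreasing = TRUE)
  if (length(fr) == 0L) return(integer(0))
  bands <- numeric(0)
  group <- fr[1L]
  for (x in fr[-1L]) {
    joins <- if (transitive) comigrates(x, group[length(group)], gel)
             else all(comigrates(x, group, gel))
    if (joins) {
      group <- c(group, x)
    } else {
      bands <- c(bands, mean(group))
      group <- x
    }
  }
  bands <- c(bands, mean(group))
  as.integer(round_half_up(bands))
}
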