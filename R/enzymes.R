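# Restriction enzyme definitions.

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition sequence, length >= 4.
#' @param cut_offset Bases from the 5' end of the recognition site to the cut
#'   position on the given strand; must lie in `[0, nchar(recognition)]`.
#' @param incubation_temp Incubation temperature in degrees Celsius
#'   (metadata only; never used in computation).
#' @return An object of class `restriction_enzyme`.
#' @export
#' @examples
#' restriction_enzyme("TaqI", "TCGA", 1, 65)
restriction_enzyme <- function(name, recognition, cut_offset,
                               incubation_temp = NA_real_) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) {
    stop("recognition sequence must be at least 4 nt", call. = FALSE)
  }
  seq_to_masks(recognition, label = paste0("enzyme ", name))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  }
  structure(
    list(name = name, recognition = recognition,
         cut_offset = cut_offset, incubation_temp = incubation_temp),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  rec <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s (%s, %s°C)\n",
              x$name, rec, format(x$incubation_temp)))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' The three enzymes used for community-level ITS2 discrimination:
#' TaqI (T^CGA, 65 C), HaeIII (GG^CC, 37 C) and MluCI (^AATT, 37 C). All
#' three recognition sites are palindromic, so single-strand scanning finds
#' every cut.
#'
#' @return Named list of `restriction_enzyme` objects.
#' @export
builtin_enzymes <- function() {
  list(
    TaqI   = restriction_enzyme("TaqI",   "TCGA", 1L, 65),
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2L, 37),
    MluCI  = restriction_enzyme("MluCI",  "AATT", 0L, 37)
  )
}

#' Read enzyme definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `recognition`,
#' `cut_offset` and optionally `temp`.
#'
#' @param path Path to a JSON file.
#' @return Named list of `restriction_enzyme` objects.
#' @export
read_enzyme_config <- function(path) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  enzymes <- lapply(defs, function(d) {
    restriction_enzyme(d$name, d$recognition, d$cut_offset,
                       incubation_temp = if (is.null(d$temp)) NA_real_ else d$temp)
  })
  stats::setNames(enzymes, vapply(enzymes, `[[`, "", "name"))
}

## Resolve a panel argument: a list of restriction_enzyme objects, or a
## character vector of built-in names (case-insensitive).
resolve_panel <- function(panel) {
  if (is.character(panel)) {
    builtins <- builtin_enzymes()
    idx <- match(tolower(panel), tolower(names(builtins)))
    if (anyNA(idx)) {
      stop("unknown built-in enzyme: ", panel[which(is.na(idx))[1L]],
           call. = FALSE)
    }
    panel <- builtins[idx]
  }
  if (length(panel) == 0L) stop("enzyme panel is empty", call. = FALSE)
  ok <- vapply(panel, inherits, TRUE, "restriction_enzyme")
  if (!all(ok)) stop("panel must contain restriction_enzyme objects",
                     call. = FALSE)
  nms <- vapply(panel, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate enzyme in panel: ", nms[duplicated(nms)][1L],
         call. = FALSE)
  }
  stats::setNames(panel, nms)
}
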