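# Matching observed gel banding patterns against expected single-species and
# mixture patterns from the community reference database.

#' Construct a band observation for one sample
#'
#' @param sample_id Sample label.
#' @param bands Named list: enzyme name -> numeric vector of observed band
#'   sizes in bases.
#' @param faint Optional named list parallel to `bands`: logical vector
#'   flagging faint bands.
#' @return An object of class `band_observation`.
#' @export
band_observation <- function(sample_id, bands, faint = NULL) {
  if (length(bands) == 0L || is.null(names(bands))) {
    stop("bands must be a non-empty named list (enzyme -> sizes)",
         call. = FALSE)
  }
  if (!is.null(faint) && !setequal(names(faint), names(bands))) {
    stop("faint flags must cover the same enzymes as bands", call. = FALSE)
  }
  for (enz in names(bands)) {
    b <- as.numeric(bands[[enz]])
    if (length(b) > 0L && any(b <= 0)) {
      stop("band sizes must be positive (enzyme ", enz, ")", call. = FALSE)
    }
    ord <- order(b, decreasing = TRUE)
    bands[[enz]] <- b[ord]
    if (!is.null(faint)) {
      if (length(faint[[enz]]) != length(b)) {
        stop("faint flags must parallel the band list (enzyme ", enz, ")",
             call. = FALSE)
      }
      faint[[enz]] <- as.logical(faint[[enz]])[ord]
    }
  }
  structure(list(sample_id = sample_id, bands = bands, faint = faint),
            class = "band_observation")
}

#' Expected gel pattern for a set of co-occurring species
#'
#' For each enzyme, pools the member species' fragment lists and passes the
#' union through the gel model (window filter plus comigration merging), i.e.
#' the banding pattern a mixed sample of those species would produce.
#'
#' @param species_set Character vector of species ids (subset of the
#'   database, non-empty).
#' @param db A `reference_db`.
#' @param gel A `gel_model`.
#' @param enzymes Optional subset of panel enzymes.
#' @return Named list: enzyme -> integer vector of band sizes, descending.
#' @export
expected_band_pattern <- function(species_set, db, gel = gel_model(),
                                  enzymes = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (length(species_set) == 0L) stop("empty species set", call. = FALSE)
  unknown <- setdiff(species_set, names(db$profiles))
  if (length(unknown) > 0L) {
    stop("species not in reference database: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(enzymes)) enzymes <- db$panel
  out <- lapply(enzymes, function(enz) {
    pooled <- unlist(lapply(species_set,
                            function(sp) db$profiles[[sp]]$fragments[[enz]]))
    visible_bands(pooled, gel)
  })
  stats::setNames(out, enzymes)
}

#' How well does an expected pattern explain an observed band list?
#'
#' Greedy one-to-one matching from largest to smallest: each observed band is
#' explained by the largest not-yet-consumed expected band that comigrates
#' with it. The result is `exact` when every observed and every expected band
#' is matched, `none` when no band matches, otherwise `partial`.
#'
#' @param observed,expected Numeric vectors of band sizes (any order; sorted
#'   internally).
#' @param gel A `gel_model`.
#' @return List with `status` (`"exact"`, `"partial"` or `"none"`),
#'   `explained` (count of matched observed bands), `unexplained_observed`
#'   (values), `unmatched_expected` (values).
#' @export
pattern_explains <- function(observed, expected, gel = gel_model()) {
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  exp <- sort(as.numeric(expected), decreasing = TRUE)
  consumed <- logical(length(exp))
  matched <- logical(length(obs))
  for (i in seq_along(obs)) {
    for (j in seq_along(exp)) {
      if (!consumed[j] && comigrates(obs[i], exp[j], gel)) {
        consumed[j] <- TRUE
        matched[i] <- TRUE
        break
      }
    }
  }
  n_exp <- sum(matched)
  status <- if (all(matched) && all(consumed)) "exact"
            else if (n_exp == 0L) "none"
            else "partial"
  list(status = status,
       explained = n_exp,
       unexplained_observed = obs[!matched],
       unmatched_expected = exp[!consumed])
}

#' Identify the host-plant species set explaining a banding pattern
#'
#' Enumerates all subsets of the community of size `1..max_mixture` and
#' tests whether each subset's expected pattern exactly explains the
#' observation for every enzyme present. All exact explanations of minimal
#' cardinality become the candidate sets (parsimony: a single species that
#' explains the bands is preferred over a pair). With one candidate the
#' status is `unique`; with several, `ambiguous` (in practice resolved by
#' sequencing); with none, `no_match`, and the best partial explanation is
#' reported -- the subset maximising the number of explained observed bands,
#' ties broken by smaller subset, then fewer unmatched expected bands, then
#' lexicographic species order.
#'
#' @param obs A `band_observation` whose enzymes are all in the database
#'   panel.
#' @param db A `reference_db` for the sample's community.
#' @param gel A `gel_model`.
#' @param max_mixture Largest mixture size considered (default 4).
#' @param include_faint Include bands flagged as faint (default `TRUE`).
#'   When `FALSE`, faint bands are dropped before matching.
#' @param cache Optional environment used to memoise expected patterns
#'   across samples from the same community (see [pattern_cache()]).
#' @return An object of class `identification_result` with `sample_id`,
#'   `status`, `candidate_sets`, `best_partial`, `unexplained_bands` and
#'   `requires_sequencing`.
#' @export
identify_sample <- function(obs, db, gel = gel_model(), max_mixture = 4L,
                            include_faint = TRUE, cache = NULL) {
  stopifnot(inherits(obs, "band_observation"), inherits(db, "reference_db"))
  enzymes <- names(obs$bands)
  extra <- setdiff(enzymes, db$panel)
  if (length(extra) > 0L) {
    stop("observation uses enzyme(s) absent from the database panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  bands <- obs$bands
  if (!include_faint && !is.null(obs$faint)) {
    for (enz in enzymes) {
      keep <- !obs$faint[[enz]]
      bands[[enz]] <- bands[[enz]][keep]
    }
  }

  species <- sort(names(db$profiles))
  max_mixture <- min(max_mixture, length(species))

  get_pattern <- function(subset) {
    if (is.null(cache)) {
      return(expected_band_pattern(subset, db, gel, enzymes = enzymes))
    }
    key <- paste(subset, collapse = "\r")
    pat <- cache[[key]]
    if (is.null(pat)) {
      pat <- expected_band_pattern(subset, db, gel, enzymes = db$panel)
      cache[[key]] <- pat
    }
    pat[enzymes]
  }

  exact_sets <- list()
  best <- NULL  # best partial bookkeeping
  for (size in seq_len(max_mixture)) {
    subsets <- utils::combn(species, size, simplify = FALSE)
    for (subset in subsets) {
      pat <- get_pattern(subset)
      all_exact <- TRUE
      tot_explained <- 0L
      tot_unmatched <- 0L
      unexplained <- stats::setNames(vector("list", length(enzymes)), enzymes)
      for (enz in enzymes) {
        res <- pattern_explains(bands[[enz]], pat[[enz]], gel)
        if (res$status != "exact") all_exact <- FALSE
        tot_explained <- tot_explained + res$explained
        tot_unmatched <- tot_unmatched + length(res$unmatched_expected)
        unexplained[[enz]] <- res$unexplained_observed
      }
      if (all_exact) {
        exact_sets[[length(exact_sets) + 1L]] <- subset
      } else if (length(exact_sets) == 0L) {
        key <- c(-tot_explained, length(subset), tot_unmatched)
        if (is.null(best) || better_partial(key, subset, best)) {
          best <- list(key = key, subset = subset, unexplained = unexplained)
        }
      }
    }
    if (length(exact_sets) > 0L) break  # minimal cardinality reached
  }

  if (length(exact_sets) > 0L) {
    status <- if (length(exact_sets) == 1L) "unique" else "ambiguous"
    return(identification_result(
      sample_id = obs$sample_id, status = status,
      candidate_sets = exact_sets, best_partial = NULL,
      unexplained_bands = NULL))
  }
  identification_result(
    sample_id = obs$sample_id, status = "no_match",
    candidate_sets = list(),
    best_partial = if (is.null(best)) character(0) else best$subset,
    unexplained_bands = if (is.null(best)) NULL else best$unexplained)
}

## Is candidate (key, subset) better than current best? Keys are compared
## lexicographically; final tie-break is species order.
better_partial <- function(key, subset, best) {
  for (i in seq_along(key)) {
    if (key[i] < best$key[i]) return(TRUE)
    if (key[i] > best$key[i]) return(FALSE)
  }
  paste(subset, collapse = ",") < paste(best$subset, collapse = ",")
}

identification_result <- function(sample_id, status, candidate_sets,
                                  best_partial, unexplained_bands) {
  structure(
    list(sample_id = sample_id,
         status = status,
         candidate_sets = candidate_sets,
         best_partial = best_partial,
         unexplained_bands = unexplained_bands,
         requires_sequencing = status != "unique"),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> %s: %s\n", x$sample_id, x$status))
  for (s in x$candidate_sets) {
    cat("  candidate: {", paste(s, collapse = ", "), "}\n", sep = "")
  }
  if (x$status == "no_match" && length(x$best_partial) > 0L) {
    cat("  best partial: {", paste(x$best_partial, collapse = ", "), "}\n",
        sep = "")
  }
  if (x$requires_sequencing) cat("  requires sequencing\n")
  invisible(x)
}

#' Create a memoisation cache for expected band patterns
#'
#' Pass the returned environment to repeated [identify_sample()] calls on
#' samples from the same community to avoid recomputing subset patterns.
#'
#' @return An empty environment.
#' @export
pattern_cache <- function() new.env(parent = emptyenv())
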