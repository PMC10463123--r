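# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (character loops, set expansion, recursion) and shares
# no code with the package internals it checks.

## IUPAC code -> base set, written out explicitly.
oracle_base_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_compatible <- function(a, b) {
  length(intersect(oracle_base_sets[[a]], oracle_base_sets[[b]])) > 0L
}

## Brute-force window scan: 0-based starts where query is compatible.
oracle_find_sites <- function(template, query) {
  tc <- strsplit(toupper(template), "")[[1]]
  qc <- strsplit(toupper(query), "")[[1]]
  n <- length(tc); m <- length(qc)
  hits <- integer(0)
  if (m > n) return(hits)
  for (s in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!oracle_compatible(tc[s + j], qc[j])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

## Brute-force digestion: split the string at every cut position.
oracle_digest <- function(residues, recognition, cut_offset) {
  sites <- oracle_find_sites(residues, recognition)
  cuts <- sort(unique(sites + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < nchar(residues)]
  pieces <- character(0)
  prev <- 0
  for (cut in c(cuts, nchar(residues))) {
    pieces <- c(pieces, substr(residues, prev + 1, cut))
    prev <- cut
  }
  sort(nchar(pieces), decreasing = TRUE)
}

## Naive gel: window filter then complete-linkage merging, recursively.
oracle_visible_bands <- function(fragments, min_size = 25, max_size = 766,
                                 rel_tol = 0.05) {
  fr <- sort(fragments[fragments >= min_size & fragments <= max_size],
             decreasing = TRUE)
  if (length(fr) == 0) return(integer(0))
  groups <- list()
  for (x in fr) {
    placed <- FALSE
    if (length(groups) > 0) {
      g <- groups[[length(groups)]]
      if (all(abs(x - g) <= rel_tol * pmax(x, g))) {
        groups[[length(groups)]] <- c(g, x)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- x
  }
  vapply(groups, function(g) as.integer(floor(mean(g) + 0.5)), 1L)
}

## Naive greedy pattern match (same contract as pattern_explains).
oracle_explains <- function(observed, expected, rel_tol = 0.05) {
  obs <- sort(observed, decreasing = TRUE)
  exp <- sort(expected, decreasing = TRUE)
  used <- rep(FALSE, length(exp))
  hit <- rep(FALSE, length(obs))
  for (i in seq_along(obs)) {
    for (j in seq_along(exp)) {
      if (!used[j] && abs(obs[i] - exp[j]) <= rel_tol * max(obs[i], exp[j])) {
        used[j] <- TRUE; hit[i] <- TRUE; break
      }
    }
  }
  list(exact = all(hit) && all(used), explained = sum(hit),
       unmatched_expected = sum(!used))
}

## Exhaustive identification oracle over all subsets of size <= max_mixture.
oracle_identify <- function(bands, db, rel_tol = 0.05, max_mixture = 4,
                            min_size = 25, max_size = 766) {
  species <- sort(names(db$profiles))
  pattern_for <- function(subset, enz) {
    pooled <- unlist(lapply(subset, function(sp) db$profiles[[sp]]$fragments[[enz]]))
    oracle_visible_bands(pooled, min_size, max_size, rel_tol)
  }
  exact <- list()
  partial <- list()
  for (size in seq_len(min(max_mixture, length(species)))) {
    for (subset in utils::combn(species, size, simplify = FALSE)) {
      all_exact <- TRUE
      tot_expl <- 0
      tot_unm <- 0
      for (enz in names(bands)) {
        r <- oracle_explains(bands[[enz]], pattern_for(subset, enz), rel_tol)
        if (!r$exact) all_exact <- FALSE
        tot_expl <- tot_expl + r$explained
        tot_unm <- tot_unm + r$unmatched_expected
      }
      if (all_exact) exact[[length(exact) + 1]] <- subset
      partial[[length(partial) + 1]] <-
        list(subset = subset, explained = tot_expl, unmatched = tot_unm)
    }
  }
  if (length(exact) > 0) {
    minsize <- min(vapply(exact, length, 1L))
    cands <- Filter(function(s) length(s) == minsize, exact)
    status <- if (length(cands) == 1) "unique" else "ambiguous"
    return(list(status = status, candidate_sets = cands))
  }
  keys <- vapply(partial, function(p) {
    sprintf("%06d|%02d|%06d|%s", 999999 - p$explained, length(p$subset),
            p$unmatched, paste(p$subset, collapse = ","))
  }, "")
  best <- partial[[order(keys)[1]]]
  list(status = "no_match", candidate_sets = list(),
       best_partial = best$subset)
}

## ---- fixture builders -------------------------------------------------

## Filler with no TaqI/HaeIII/MluCI site and no primer match ("CACA...").
filler <- function(n) paste(rep(c("C", "A"), length.out = n), collapse = "")

## Wrap an arbitrary residue string as an amplicon object.
make_amplicon <- function(species_id, residues) {
  structure(list(species_id = species_id, residues = residues,
                 length = nchar(residues), start = 0L,
                 end = nchar(residues)),
            class = "amplicon")
}

## A reference_db built directly from amplicon residue strings.
make_db <- function(residue_list, panel = builtin_enzymes(),
                    community_id = "fixture") {
  panel <- rflpdiet:::resolve_panel(panel)
  profiles <- lapply(names(residue_list), function(id) {
    build_profile(make_amplicon(id, residue_list[[id]]), panel)
  })
  structure(list(community_id = community_id, panel = names(panel),
                 enzymes = panel,
                 profiles = setNames(profiles, names(residue_list))),
            class = "reference_db")
}

## Template with the ITS2 primer sites around an insert.
make_template <- function(insert, prefix = "AAA", suffix = "CCC",
                          primers = its_primers()) {
  paste0(prefix, primers$forward, insert,
         reverse_complement(primers$reverse), suffix)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## 3-species db where TaqI separates a|b and a|c, HaeIII separates pairs
## involving c, MluCI nothing: no single enzyme is complete and the only
## complete 2-enzyme subset is {HaeIII, TaqI}.
panel_fixture <- function() {
  make_db(list(
    a = paste0(filler(100), "TCGA", filler(200)),
    b = paste0(filler(50), "TCGA", filler(250)),
    c = paste0(filler(50), "TCGA", filler(96), "GGCC", filler(150))
  ))
}
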