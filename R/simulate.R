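# Synthetic mesocosm experiment generator. Emulates the structure the
# analysis assumes: ITS-like reference sequences flanked by the primer
# sites, small plant communities replicated across mesocosms, repeated
# faecal/regurgitate sampling of one female and one male grasshopper per
# mesocosm, amplification success by sample type and sex, diet-set sizes
# drawn from a fixed count distribution, and multiplicative gel sizing
# noise within the detection window.

#' Configuration for a simulated mesocosm experiment
#'
#' Defaults state the emulated experiment: a pool of 39 species (19 native,
#' 20 exotic), 20 communities of 8 species replicated 4 times, 4 sampling
#' occasions, amplicons of 400-600 bp, 10% pairwise sequence divergence with
#' one near-identical species pair (emulating congeners too similar for
#' RFLP), amplification success probabilities by sample type and sex taken
#' from the study's group means, diet-set sizes weighted 335:133:31:1 for
#' 1-4 species, and 2% relative gel sizing noise.
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param n_species Size of the species pool.
#' @param n_natives Number of native species (the rest are exotic).
#' @param n_communities Number of distinct communities.
#' @param community_size Species per community.
#' @param replicates Mesocosm replicates per community.
#' @param n_occasions Sampling occasions.
#' @param amplicon_length_range Length range (bases) for generated amplicons.
#' @param divergence Per-base substitution probability from the ancestral
#'   sequence for ordinary species.
#' @param near_identical_pairs Number of species pairs generated at
#'   `near_identical_divergence` from each other.
#' @param near_identical_divergence Per-base divergence within such a pair.
#' @param amplification_probs Named vector `faecal.female`,
#'   `regurgitate.female`, `faecal.male`, `regurgitate.male` of
#'   amplification success probabilities.
#' @param species_count_weights Named weights for diet-set sizes 1..k.
#' @param sizing_noise_sd Relative standard deviation of observed band size.
#' @param shared_diet_prob Probability that a grasshopper's regurgitate
#'   sample reflects the same true diet set as its faecal sample on that
#'   occasion (0 = independent draws, the default).
#' @param sla_bias Detection-bias factor: when positive, faecal (but not
#'   regurgitate) diet draws are weighted towards low specific-leaf-area
#'   species by `exp(-sla_bias * z(SLA))`.
#' @param thinning Probability that a scheduled sample is not collected
#'   (emulating missed captures; default 0, balanced design).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 39L,
                       n_natives = 19L,
                       n_communities = 20L,
                       community_size = 8L,
                       replicates = 4L,
                       n_occasions = 4L,
                       amplicon_length_range = c(400L, 600L),
                       divergence = 0.10,
                       near_identical_pairs = 1L,
                       near_identical_divergence = 0.005,
                       amplification_probs = c(faecal.female = 0.773,
                                               regurgitate.female = 0.630,
                                               faecal.male = 0.801,
                                               regurgitate.male = 0.431),
                       species_count_weights = c("1" = 335, "2" = 133,
                                                 "3" = 31, "4" = 1),
                       sizing_noise_sd = 0.02,
                       shared_diet_prob = 0,
                       sla_bias = 0,
                       thinning = 0) {
  stopifnot(community_size <= n_species,
            n_natives <= n_species,
            all(amplification_probs >= 0 & amplification_probs <= 1),
            all(species_count_weights >= 0),
            sum(species_count_weights) > 0,
            divergence >= 0, divergence <= 1,
            sizing_noise_sd >= 0,
            shared_diet_prob >= 0, shared_diet_prob <= 1,
            thinning >= 0, thinning < 1)
  needed <- c("faecal.female", "regurgitate.female",
              "faecal.male", "regurgitate.male")
  if (!all(needed %in% names(amplification_probs))) {
    stop("amplification_probs must name all four type.sex groups",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         n_natives = as.integer(n_natives),
         n_communities = as.integer(n_communities),
         community_size = as.integer(community_size),
         replicates = as.integer(replicates),
         n_occasions = as.integer(n_occasions),
         amplicon_length_range = as.integer(amplicon_length_range),
         divergence = divergence,
         near_identical_pairs = as.integer(near_identical_pairs),
         near_identical_divergence = near_identical_divergence,
         amplification_probs = amplification_probs,
         species_count_weights = species_count_weights,
         sizing_noise_sd = sizing_noise_sd,
         shared_diet_prob = shared_diet_prob,
         sla_bias = sla_bias,
         thinning = thinning),
    class = "sim_config"
  )
}

species_ids <- function(config) sprintf("sp%02d", seq_len(config$n_species))

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Independent per-base substitution at the given rate; substitutions are
## uniform over the three other bases.
mutate_seq <- function(residues, rate) {
  if (rate <= 0) return(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

#' Generate synthetic reference sequences
#'
#' Builds a random ancestral insert, derives each species by independent
#' per-base substitution at the configured divergence, and flanks every
#' insert with the ITS2 primer sites (plus short random tails) so amplicon
#' extraction succeeds. Designated near-identical pairs -- species
#' `(1, 2)`, `(3, 4)`, ... up to `near_identical_pairs` -- use the reduced
#' within-pair divergence, emulating congeners that RFLP cannot separate.
#' Templates are checked to carry exactly one site per primer; a species
#' creating a spurious priming site is redrawn. Deterministic under the
#' config seed.
#'
#' @param config A `sim_config`.
#' @param primers A `primer_pair` (default [its_primers()]).
#' @return A `ref_seqs` collection, one template per species.
#' @export
generate_reference_sequences <- function(config, primers = its_primers()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  flank <- nchar(primers$forward) + nchar(primers$reverse)
  lo <- max(1L, config$amplicon_length_range[1L] - flank)
  hi <- max(lo, config$amplicon_length_range[2L] - flank)
  insert_len <- if (hi > lo) sample(lo:hi, 1L) else lo
  ancestor <- random_bases(insert_len)
  rc_rev <- reverse_complement(primers$reverse)

  ids <- species_ids(config)
  pair_second <- integer(0)
  if (config$near_identical_pairs > 0L) {
    k <- seq_len(min(config$near_identical_pairs,
                     floor(config$n_species / 2)))
    pair_second <- 2L * k  # derived from species 2k - 1
  }

  inserts <- character(config$n_species)
  templates <- character(config$n_species)
  for (i in seq_len(config$n_species)) {
    for (try in 1:50) {
      ins <- if (i %in% pair_second) {
        mutate_seq(inserts[i - 1L], config$near_identical_divergence)
      } else {
        mutate_seq(ancestor, config$divergence)
      }
      tmpl <- paste0(random_bases(10L), primers$forward, ins, rc_rev,
                     random_bases(10L))
      fwd <- find_primer_sites(tmpl, primers$forward, "forward")
      rev <- find_primer_sites(tmpl, primers$reverse, "reverse")
      if (length(fwd) == 1L && length(rev) == 1L) break
      if (try == 50L) stop("could not build a cleanly priming template",
                           call. = FALSE)
    }
    inserts[i] <- ins
    templates[i] <- tmpl
  }
  ref_seqs(stats::setNames(templates, ids),
           descriptions = rep("synthetic ITS-like template",
                              config$n_species))
}

#' Generate community membership lists
#'
#' Draws `n_communities` distinct species sets of `community_size`, each
#' uniform without replacement from the pool. Deterministic under the
#' config seed.
#'
#' @param config A `sim_config`.
#' @return Named list of character vectors (community id -> species ids).
#' @export
generate_communities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (choose(config$n_species, config$community_size) < config$n_communities) {
    stop("species pool too small for that many distinct communities",
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  ids <- species_ids(config)
  seen <- character(0)
  communities <- vector("list", config$n_communities)
  i <- 1L
  while (i <= config$n_communities) {
    comm <- sort(sample(ids, config$community_size))
    key <- paste(comm, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      communities[[i]] <- comm
      i <- i + 1L
    }
  }
  stats::setNames(communities,
                  sprintf("comm%02d", seq_len(config$n_communities)))
}

#' Generate species trait table
#'
#' Provenance follows the configured native/exotic split; functional group
#' is drawn herbaceous-biased (4:1, grassland-like); specific leaf area is
#' log-normal around 15 mm2/mg (sdlog 0.4), spanning the range typical of
#' temperate grassland floras. Deterministic under the config seed.
#'
#' @param config A `sim_config`.
#' @return Data frame with `species_id`, `provenance`, `functional_group`,
#'   `specific_leaf_area`.
#' @export
generate_species_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ids <- species_ids(config)
  provenance <- c(rep("native", config$n_natives),
                  rep("exotic", config$n_species - config$n_natives))
  data.frame(
    species_id = ids,
    provenance = provenance,
    functional_group = sample(c("herbaceous", "woody"), config$n_species,
                              replace = TRUE, prob = c(0.8, 0.2)),
    specific_leaf_area = stats::rlnorm(config$n_species,
                                       meanlog = log(15), sdlog = 0.4),
    stringsAsFactors = FALSE)
}

## Draw one diet set from a community. `weights` are per-species sampling
## weights (NULL = uniform).
draw_diet_set <- function(community, size_probs, weights = NULL) {
  k <- sample.int(length(size_probs), 1L, prob = size_probs)
  k <- min(k, length(community))
  sort(sample(community, k, prob = weights))
}

#' Simulate a full mesocosm feeding experiment
#'
#' For every mesocosm (community x replicate) and occasion, one female and
#' one male grasshopper each contribute one faecal and one regurgitate
#' sample. Each sample's true diet set is drawn from the configured
#' set-size weights with members uniform within the community (optionally
#' biased by specific leaf area for faecal samples, and optionally shared
#' between a grasshopper's paired samples). Amplification success is
#' Bernoulli by sample type and sex. For amplified samples, observed bands
#' are the expected pattern of the true set perturbed by multiplicative
#' Gaussian sizing noise and filtered to the gel detection window.
#' Deterministic under the config seed.
#'
#' @param config A `sim_config`.
#' @param gel A `gel_model` used for pattern generation and windowing.
#' @param primers A `primer_pair`.
#' @param panel Enzyme panel (default the three built-ins).
#' @param make_observations Generate reference sequences, databases and
#'   band observations (default `TRUE`). With `FALSE` only the sampling
#'   design, truth sets and amplification outcomes are simulated, which is
#'   much faster and leaves the record table identical for the same seed.
#' @return An object of class `simulated_experiment`: list with `config`,
#'   `sequences`, `communities`, `traits`, `dbs` (per-community
#'   `reference_db`), `records` (a `sample_records` data frame with a
#'   `community_id` column), `truth` (list of true species sets, parallel to
#'   records) and `observations` (named list of `band_observation` for
#'   amplified samples).
#' @export
simulate_experiment <- function(config,
                                gel = gel_model(),
                                primers = its_primers(),
                                panel = builtin_enzymes(),
                                make_observations = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  communities <- generate_communities(config)
  traits <- generate_species_traits(config)

  sequences <- NULL
  dbs <- NULL
  if (make_observations) {
    sequences <- generate_reference_sequences(config, primers)
    dbs <- lapply(names(communities), function(cid) {
      build_reference_db(sequences, communities[[cid]], primers, panel,
                         community_id = cid)
    })
    names(dbs) <- names(communities)
  }

  ## sampling design
  design <- expand.grid(
    occasion = seq_len(config$n_occasions),
    sample_type = c("faecal", "regurgitate"),
    sex = c("female", "male"),
    replicate = seq_len(config$replicates),
    community = seq_len(config$n_communities),
    stringsAsFactors = FALSE)
  ## order: community, replicate, occasion, sex, then faecal before
  ## regurgitate so shared-diet draws can copy the faecal set
  design <- design[order(design$community, design$replicate,
                         design$occasion, design$sex,
                         design$sample_type), , drop = FALSE]
  n <- nrow(design)
  design$community_id <- sprintf("comm%02d", design$community)
  design$mesocosm_id <- sprintf("meso_%02d_%d",
                                design$community, design$replicate)
  design$grasshopper_id <- paste(design$mesocosm_id,
                                 substr(design$sex, 1, 1), sep = "_")
  design$sample_id <- sprintf("s%04d", seq_len(n))

  size_probs <- config$species_count_weights /
    sum(config$species_count_weights)

  set.seed(config$seed + 3L)
  truth <- vector("list", n)
  amplified <- logical(n)
  collected <- rep(TRUE, n)
  last_faecal_set <- NULL
  for (i in seq_len(n)) {
    comm <- communities[[design$community_id[i]]]
    weights <- NULL
    if (config$sla_bias > 0 && design$sample_type[i] == "faecal") {
      sla <- traits$specific_leaf_area[match(comm, traits$species_id)]
      z <- (sla - mean(sla)) / stats::sd(sla)
      weights <- exp(-config$sla_bias * z)
    }
    if (design$sample_type[i] == "faecal") {
      truth[[i]] <- draw_diet_set(comm, size_probs, weights)
      last_faecal_set <- truth[[i]]
    } else {
      ## regurgitate row always follows its paired faecal row
      if (config$shared_diet_prob > 0 &&
          stats::runif(1L) < config$shared_diet_prob) {
        truth[[i]] <- last_faecal_set
      } else {
        truth[[i]] <- draw_diet_set(comm, size_probs, NULL)
      }
    }
    p <- config$amplification_probs[[paste(design$sample_type[i],
                                           design$sex[i], sep = ".")]]
    amplified[i] <- stats::runif(1L) < p
    if (config$thinning > 0) {
      collected[i] <- stats::runif(1L) >= config$thinning
    }
  }

  observations <- list()
  if (make_observations) {
    caches <- lapply(dbs, function(d) pattern_cache())
    for (i in seq_len(n)) {
      if (!amplified[i] || !collected[i]) next
      cid <- design$community_id[i]
      cache <- caches[[cid]]
      key <- paste(truth[[i]], collapse = "\r")
      pat <- cache[[key]]
      if (is.null(pat)) {
        pat <- expected_band_pattern(truth[[i]], dbs[[cid]], gel)
        cache[[key]] <- pat
      }
      noisy <- lapply(pat, function(bands) {
        if (length(bands) == 0L) return(numeric(0))
        b <- bands * (1 + stats::rnorm(length(bands),
                                       sd = config$sizing_noise_sd))
        b <- round_half_up(b)
        b[b >= gel$min_size & b <= gel$max_size]
      })
      observations[[design$sample_id[i]]] <-
        band_observation(design$sample_id[i], noisy)
    }
  }

  keep <- collected
  records <- sample_records(
    sample_id = design$sample_id[keep],
    grasshopper_id = design$grasshopper_id[keep],
    mesocosm_id = design$mesocosm_id[keep],
    occasion = design$occasion[keep],
    sample_type = design$sample_type[keep],
    sex = design$sex[keep],
    amplified = amplified[keep],
    identified = rep(FALSE, sum(keep)))
  records$community_id <- design$community_id[keep]

  structure(
    list(config = config, sequences = sequences, communities = communities,
         traits = traits, dbs = dbs, records = records,
         truth = stats::setNames(truth[keep], design$sample_id[keep]),
         observations = observations),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(
    "<simulated_experiment> %d samples (%d amplified), %d communities\n",
    nrow(x$records), sum(x$records$amplified), length(x$communities)))
  invisible(x)
}

#' Run RFLP identification over a simulated experiment
#'
#' Applies [identify_sample()] to every amplified sample's band observation,
#' using a per-community pattern cache. Samples with a unique explanation
#' are identified by RFLP alone; ambiguous samples are escalated to
#' "sequencing", which the simulator resolves with the known truth when the
#' true set is among the candidates (mirroring how ambiguous banding
#' patterns are resolved in practice).
#'
#' @param experiment A `simulated_experiment` built with observations.
#' @param gel A `gel_model`.
#' @param max_mixture Largest mixture size considered.
#' @param sequence_ambiguous Resolve ambiguous samples with the true set
#'   when it is a candidate (default `TRUE`).
#' @return The experiment's `records` data frame with `identified`,
#'   `species_set` filled in and extra columns `status` and `rflp_only`.
#' @export
identify_experiment <- function(experiment, gel = gel_model(),
                                max_mixture = 4L,
                                sequence_ambiguous = TRUE) {
  stopifnot(inherits(experiment, "simulated_experiment"))
  if (is.null(experiment$dbs)) {
    stop("experiment was simulated without observations", call. = FALSE)
  }
  rec <- experiment$records
  n <- nrow(rec)
  status <- rep("not_amplified", n)
  rflp_only <- rep(NA, n)
  sets <- replicate(n, character(0), simplify = FALSE)
  identified <- rep(FALSE, n)
  caches <- lapply(experiment$dbs, function(d) pattern_cache())
  for (i in seq_len(n)) {
    if (!rec$amplified[i]) next
    obs <- experiment$observations[[rec$sample_id[i]]]
    if (is.null(obs)) next
    cid <- rec$community_id[i]
    res <- identify_sample(obs, experiment$dbs[[cid]], gel,
                           max_mixture = max_mixture,
                           cache = caches[[cid]])
    status[i] <- res$status
    if (res$status == "unique") {
      sets[[i]] <- res$candidate_sets[[1L]]
      identified[i] <- TRUE
      rflp_only[i] <- TRUE
    } else if (res$status == "ambiguous" && sequence_ambiguous) {
      truth <- experiment$truth[[rec$sample_id[i]]]
      hit <- any(vapply(res$candidate_sets,
                        function(s) setequal(s, truth), TRUE))
      if (hit) {
        sets[[i]] <- truth
        identified[i] <- TRUE
        rflp_only[i] <- FALSE
      }
    }
  }
  rec$identified <- identified
  rec$species_set <- sets
  rec$status <- status
  rec$rflp_only <- rflp_only
  rec
}
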