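# Synthetic mesocosm experiment generator.

test_that("generators are deterministic under the config seed", {
  cfg <- sim_config(seed = 99, n_species = 8, n_natives = 4,
                    n_communities = 3, community_size = 4, replicates = 2)
  expect_identical(generate_reference_sequences(cfg),
                   generate_reference_sequences(cfg))
  expect_identical(generate_communities(cfg), generate_communities(cfg))
  expect_identical(generate_species_traits(cfg),
                   generate_species_traits(cfg))
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$observations, e2$observations)
  # and a byte-identical FASTA
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(generate_reference_sequences(cfg), f1)
  write_fasta(generate_reference_sequences(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero divergence collapses the pool to identical sequences", {
  cfg <- sim_config(seed = 5, n_species = 4, n_natives = 2,
                    n_communities = 1, community_size = 4,
                    divergence = 0, near_identical_pairs = 0)
  refs <- generate_reference_sequences(cfg)
  amps <- extract_amplicons(refs, its_primers())
  inner <- vapply(amps, `[[`, "", "residues")
  expect_true(all(inner == inner[1]))
  db <- build_reference_db(refs, names(refs))
  rep <- select_panel(db)
  expect_equal(rep$distinguishable_pairs, 0L)
  expect_length(rep$indistinguishable, choose(4, 2))
})

test_that("amplicon lengths fall in the configured range", {
  cfg <- sim_config(seed = 12, n_species = 6, n_natives = 3,
                    n_communities = 1, community_size = 6,
                    near_identical_pairs = 1)
  refs <- generate_reference_sequences(cfg)
  amps <- extract_amplicons(refs, its_primers())
  lens <- vapply(amps, `[[`, 1L, "length")
  expect_true(all(lens >= 400 & lens <= 600))
  expect_equal(length(unique(lens)), 1L)  # shared ancestral insert length
})

test_that("pairwise identity tracks the substitution model", {
  # two sequences mutated independently from one ancestor at rate d agree
  # per base with probability (1-d)^2 + d^2/3
  d <- 0.10
  expected <- (1 - d)^2 + d^2 / 3
  idents <- c()
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_species = 8, n_natives = 4,
                      n_communities = 1, community_size = 8,
                      divergence = d, near_identical_pairs = 0)
    amps <- extract_amplicons(generate_reference_sequences(cfg),
                              its_primers())
    inner <- lapply(amps, function(a) {
      strsplit(substr(a$residues, 21, a$length - 21), "")[[1]]
    })
    for (p in utils::combn(length(inner), 2, simplify = FALSE)) {
      idents <- c(idents, mean(inner[[p[1]]] == inner[[p[2]]]))
    }
  }
  expect_lt(abs(mean(idents) - expected), 0.03)
})

test_that("near-identical pairs are generated at the reduced divergence", {
  cfg <- sim_config(seed = 23, n_species = 8, n_natives = 4,
                    n_communities = 1, community_size = 8,
                    near_identical_pairs = 1)
  amps <- extract_amplicons(generate_reference_sequences(cfg),
                            its_primers())
  ident <- function(a, b) {
    x <- strsplit(a$residues, "")[[1]]; y <- strsplit(b$residues, "")[[1]]
    mean(x == y)
  }
  expect_gt(ident(amps$sp01, amps$sp02), 0.98)   # the designated pair
  expect_lt(ident(amps$sp01, amps$sp03), 0.95)   # ordinary divergence
})

test_that("generate_communities draws distinct sets of the right size", {
  cfg <- sim_config(seed = 3)
  comms <- generate_communities(cfg)
  expect_length(comms, 20)
  expect_true(all(vapply(comms, length, 1L) == 8L))
  keys <- vapply(comms, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(unlist(comms) %in% sprintf("sp%02d", 1:39)))
  # full pool as single community
  cfg2 <- sim_config(seed = 3, n_species = 6, n_natives = 3,
                     n_communities = 1, community_size = 6)
  expect_equal(generate_communities(cfg2)[[1]], sprintf("sp%02d", 1:6))
  expect_error(generate_communities(
    sim_config(seed = 1, n_species = 4, n_natives = 2, n_communities = 10,
               community_size = 4)), "too small")
})

test_that("design counting identity holds when everything amplifies", {
  cfg <- sim_config(seed = 8, n_species = 10, n_natives = 5,
                    n_communities = 4, community_size = 5, replicates = 3,
                    amplification_probs = c(faecal.female = 1,
                                            regurgitate.female = 1,
                                            faecal.male = 1,
                                            regurgitate.male = 1))
  exp <- simulate_experiment(cfg, make_observations = FALSE)
  expect_equal(nrow(exp$records), 4 * 3 * 2 * 2 * 4)
  expect_true(all(exp$records$amplified))
  # truth sets are subsets of the mesocosm's community
  for (i in seq_len(nrow(exp$records))) {
    comm <- exp$communities[[exp$records$community_id[i]]]
    expect_true(all(exp$truth[[exp$records$sample_id[i]]] %in% comm))
  }
})

test_that("observations exist exactly for amplified samples", {
  cfg <- sim_config(seed = 31, n_species = 8, n_natives = 4,
                    n_communities = 2, community_size = 4, replicates = 2)
  exp <- simulate_experiment(cfg)
  expect_setequal(names(exp$observations),
                  exp$records$sample_id[exp$records$amplified])
  # all observed bands sit inside the gel window
  for (obs in exp$observations) {
    bands <- unlist(obs$bands)
    expect_true(all(bands >= 25 & bands <= 766))
  }
})

test_that("shared_diet_prob = 1 makes paired truths identical", {
  cfg <- sim_config(seed = 13, n_species = 10, n_natives = 5,
                    n_communities = 3, community_size = 5, replicates = 2,
                    shared_diet_prob = 1)
  exp <- simulate_experiment(cfg, make_observations = FALSE)
  rec <- exp$records
  key <- paste(rec$grasshopper_id, rec$occasion)
  for (k in unique(key)) {
    sets <- exp$truth[rec$sample_id[key == k]]
    expect_equal(length(sets), 2L)
    expect_setequal(sets[[1]], sets[[2]])
  }
})

test_that("thinning drops samples", {
  cfg <- sim_config(seed = 14, n_species = 8, n_natives = 4,
                    n_communities = 3, community_size = 4, replicates = 2,
                    thinning = 0.3)
  exp <- simulate_experiment(cfg, make_observations = FALSE)
  expect_lt(nrow(exp$records), 3 * 2 * 2 * 2 * 4)
})

test_that("full pipeline reproduces the configured species-per-sample
           mean", {
  # simulate -> identify -> summarise, noiseless gel, everything amplified:
  # 20 x 7 x 4 x 2 x 2 = 2240 samples, >= 2000 identified
  cfg <- sim_config(seed = 77, replicates = 7, sizing_noise_sd = 0,
                    amplification_probs = c(faecal.female = 1,
                                            regurgitate.female = 1,
                                            faecal.male = 1,
                                            regurgitate.male = 1))
  exp <- simulate_experiment(cfg)
  rec <- identify_experiment(exp)
  expect_gte(sum(rec$identified), 2000)
  k <- vapply(rec$species_set[rec$identified], length, 1L)
  configured <- sum(1:4 * cfg$species_count_weights) /
    sum(cfg$species_count_weights)
  got <- mean_species_per_sample(table(k))
  expect_lt(abs(got$mean - configured), 0.05)
})

test_that("grouped amplification proportions recover configured truth", {
  # small-scale version of the binomial coverage property (the acceptance
  # suite runs the full-size one)
  cfg <- sim_config(seed = 44, n_species = 10, n_natives = 5,
                    n_communities = 5, community_size = 5, replicates = 2)
  covered <- 0L; total <- 0L
  for (rep in 1:50) {
    cfg$seed <- 44L + rep
    exp <- simulate_experiment(cfg, make_observations = FALSE)
    ps <- proportion_summary(exp$records, "both", success = "amplified")
    for (i in seq_len(nrow(ps))) {
      truth <- cfg$amplification_probs[[paste(ps$sample_type[i], ps$sex[i],
                                              sep = ".")]]
      covered <- covered + (truth >= ps$lower[i] && truth <= ps$upper[i])
      total <- total + 1L
    }
  }
  expect_gte(covered / total, 0.90)
})

test_that("noiseless round trip recovers every singleton truth", {
  cfg <- sim_config(seed = 55, n_species = 8, n_natives = 4,
                    n_communities = 2, community_size = 4, replicates = 1,
                    sizing_noise_sd = 0,
                    species_count_weights = c("1" = 1),
                    near_identical_pairs = 0,
                    amplification_probs = c(faecal.female = 1,
                                            regurgitate.female = 1,
                                            faecal.male = 1,
                                            regurgitate.male = 1))
  exp <- simulate_experiment(cfg)
  rec <- identify_experiment(exp)
  expect_true(all(rec$status == "unique"))
  for (i in seq_len(nrow(rec))) {
    expect_setequal(rec$species_set[[i]], exp$truth[[rec$sample_id[i]]])
  }
})
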