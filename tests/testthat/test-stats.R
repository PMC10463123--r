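# Diet summary statistics.

test_that("wilson_ci matches prop.test's score interval", {
  cases <- rbind(c(50, 100), c(0, 10), c(10, 10), c(3, 7), c(531, 801))
  for (k in seq_len(nrow(cases))) {
    x <- cases[k, 1]; n <- cases[k, 2]
    got <- wilson_ci(x, n)
    ref <- suppressWarnings(stats::prop.test(x, n, correct = FALSE))$conf.int
    expect_lt(abs(got[["lower"]] - ref[1]), 1e-12)
    expect_lt(abs(got[["upper"]] - ref[2]), 1e-12)
    expect_equal(got[["estimate"]], x / n)
    expect_gte(got[["lower"]], 0)
    expect_lte(got[["upper"]], 1)
    expect_true(got[["lower"]] <= got[["estimate"]] &&
                got[["estimate"]] <= got[["upper"]])
  }
  # hand-checked: 50/100 -> approximately (40.4%, 59.6%)
  ci <- wilson_ci(50, 100)
  expect_equal(round(100 * ci[["lower"]], 1), 40.4)
  expect_equal(round(100 * ci[["upper"]], 1), 59.6)
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
})

make_records <- function() {
  sample_records(
    sample_id = sprintf("s%02d", 1:8),
    grasshopper_id = c("g1", "g1", "g2", "g2", "g1", "g1", "g3", "g3"),
    mesocosm_id = rep("m1", 8),
    occasion = c(1, 1, 1, 1, 2, 2, 2, 2),
    sample_type = rep(c("faecal", "regurgitate"), 4),
    sex = rep(c("female", "female", "male", "male"), 2),
    amplified = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    identified = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    species_set = list(c("A", "B"), c("B", "C"), "A", character(0),
                       "D", "D", character(0), c("A", "D")))
}

test_that("proportion_summary groups and flags empty groups", {
  rec <- make_records()
  overall <- proportion_summary(rec, "none", success = "amplified")
  expect_equal(overall$n_success, 7L)
  expect_equal(overall$n_total, 8L)
  expect_equal(overall$proportion, 7 / 8)
  by_type <- proportion_summary(rec, "sample_type", success = "identified")
  expect_equal(by_type$n_total, c(4L, 4L))
  both <- proportion_summary(rec, "both")
  expect_equal(nrow(both), 4L)
  expect_false(any(both$undefined))
  # predicate-function success: identified by RFLP only would go here
  fn <- proportion_summary(rec, "none",
                           success = function(r) r$amplified & r$identified)
  expect_equal(fn$n_success, 6L)
  expect_error(proportion_summary(rec[0, ], "none"), "no records")
})

test_that("relative_difference reproduces the reporting arithmetic", {
  expect_equal(relative_difference(0.773, 0.630)$percent_rounded, 23)
  expect_equal(relative_difference(0.801, 0.431)$percent_rounded, 86)
  expect_equal(relative_difference(0.5, 0.5)$percent, 0)
  expect_equal(relative_difference(0.75, 0.5)$percent, 50)
  expect_error(relative_difference(0.5, 0), "positive")
})

test_that("pair_samples forms pairs only when both sets are non-empty", {
  rec <- make_records()
  pairs <- pair_samples(rec)
  # g1 occ1 (AB vs BC), g1 occ2 (D vs D); g2 occ1 regurgitate empty;
  # g3 occ2 faecal empty
  expect_equal(nrow(pairs), 2L)
  rates <- paired_match_rates(pairs)
  expect_equal(rates$n_pairs, 2L)
  expect_equal(rates$exact_count, 1L)   # D vs D
  expect_equal(rates$partial_count, 2L) # AB/BC share B; exact counts too
  expect_equal(rates$exact_pct, 50)
  expect_equal(rates$partial_pct, 100)
  expect_lte(rates$exact_count, rates$partial_count)
  expect_lte(rates$partial_count, rates$n_pairs)
})

test_that("paired_match_rates handles the definitional cases", {
  pairs <- data.frame(grasshopper_id = c("a", "b"), occasion = 1L)
  pairs$faecal_set <- list(c("A", "B"), "C")
  pairs$regurgitate_set <- list(c("B", "C"), "C")
  r <- paired_match_rates(pairs)
  expect_equal(r$exact_count, 1L)
  expect_equal(r$partial_count, 2L)
  identical_pairs <- data.frame(grasshopper_id = "a", occasion = 1L)
  identical_pairs$faecal_set <- list("A")
  identical_pairs$regurgitate_set <- list("A")
  r2 <- paired_match_rates(identical_pairs)
  expect_equal(r2$exact_pct, 100)
  expect_equal(r2$partial_pct, 100)
})

test_that("mean_species_per_sample is a weighted mean reported to 2 dp", {
  m <- mean_species_per_sample(c("1" = 335, "2" = 133, "3" = 31, "4" = 1))
  expect_equal(m$mean_2dp, 1.40)
  expect_equal(m$mean, 698 / 500)
  expect_equal(mean_species_per_sample(c("1" = 17))$mean_2dp, 1.00)
  expect_equal(mean_species_per_sample(c("2" = 5, "4" = 5))$mean_2dp, 3.00)
  expect_error(mean_species_per_sample(numeric(0)), "empty")
  expect_error(mean_species_per_sample(c("0" = 3)), ">= 1")
})

test_that("faecal_deviance_table counts events, filters and fills CIs", {
  n <- 14
  rec <- sample_records(
    sample_id = sprintf("s%02d", 1:n),
    grasshopper_id = rep("g", n), mesocosm_id = rep("m", n),
    occasion = rep(1L, n),
    sample_type = c(rep("faecal", 8), rep("regurgitate", 6)),
    sex = rep("female", n),
    amplified = rep(TRUE, n), identified = rep(TRUE, n),
    species_set = c(rep(list("big"), 8),
                    rep(list(c("big", "rare")), 2),
                    rep(list("other"), 4)))
  tab <- faecal_deviance_table(rec, expected_prop = 0.66, min_samples = 5)
  # big: 8 faecal of 10; rare: 2 total -> filtered; other: 4 -> filtered
  expect_equal(tab$species_id, "big")
  expect_equal(tab$n_faecal_ids, 8L)
  expect_equal(tab$n_total_ids, 10L)
  expect_equal(tab$observed_prop, 0.8)
  expect_equal(tab$deviance, 0.14)
  ci <- wilson_ci(8, 10)
  expect_equal(tab$ci_low, ci[["lower"]])
  expect_equal(tab$ci_high, ci[["upper"]])
  # lowering the filter admits the rarer species
  tab2 <- faecal_deviance_table(rec, 0.66, min_samples = 2)
  expect_setequal(tab2$species_id, c("big", "rare", "other"))
  expect_equal(tab2$deviance[tab2$species_id == "other"], -0.66)
})

test_that("pearson_chi_squared matches hand and library computation", {
  r0 <- pearson_chi_squared(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 1L)
  r1 <- pearson_chi_squared(rbind(c(20, 10), c(10, 20)))
  expect_equal(r1$statistic, 20 / 3, tolerance = 1e-12)  # N(ad-bc)^2/margins
  r2 <- pearson_chi_squared(rbind(c(5, 0), c(0, 5)))
  expect_equal(r2$statistic, 10)
  set.seed(71)
  for (rep in 1:10) {
    tab <- matrix(rpois(12, 20) + 1, nrow = 3)
    got <- pearson_chi_squared(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    # permutation invariance
    perm <- pearson_chi_squared(tab[sample(3), sample(4)])
    expect_equal(perm$statistic, got$statistic, tolerance = 1e-12)
  }
  expect_error(pearson_chi_squared(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(pearson_chi_squared(matrix(1:3, 3)), "2x2")
})

test_that("simple_linear_regression matches the normal equations and lm", {
  fit <- suppressWarnings(simple_linear_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  fit2 <- simple_linear_regression(c(0, 2, 1, 3), c(0, 1, 2, 3))
  expect_equal(fit2$slope, 0.8)
  expect_equal(fit2$intercept, 0.3)
  expect_equal(fit2$n, 4L)
  # binary trait coding: second sorted level codes 1
  fit3 <- simple_linear_regression(c(1, 2, 5, 6),
                                   c("exotic", "exotic", "native", "native"))
  expect_equal(fit3$slope, 4)
  expect_error(simple_linear_regression(c(0, 1), c(1, 0)), "at least 3")
  expect_error(simple_linear_regression(c(0, 1, 2), c(1, 1, 1)), "constant")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(1.396, 2), 1.40)
  expect_equal(round_half_up(94.538), 95)
})

test_that("sample_records enforces its invariants", {
  expect_error(sample_records("s", "g", "m", 1, "faecal", "female",
                              amplified = FALSE, identified = TRUE),
               "amplified")
  expect_error(sample_records("s", "g", "m", 1, "faecal", "female",
                              amplified = TRUE, identified = FALSE,
                              species_set = list("A")),
               "implies identification")
})
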