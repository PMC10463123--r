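# Diet summary statistics: success proportions, paired-sample agreement,
# species-per-sample means, detection-bias deviance, contingency tests and
# trait regression.

#' Round half away from zero
#'
#' Presentation rounding used for all reported percentages (base `round()`
#' rounds half to even, which is not the convention used in reporting).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Preferred over the Wald interval for the small per-species counts that
#' arise near the minimum-sample filter.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries the score bound is exactly the point (up to rounding)
  lower <- if (x == 0) 0 else max(0, centre - half)
  upper <- if (x == n) 1 else min(1, centre + half)
  c(estimate = p, lower = lower, upper = upper)
}

#' Assemble a sample-record table
#'
#' One row per collected sample. `species_set` is a list column of character
#' vectors (possibly empty). Enforces the logical chain: an identified sample
#' must have amplified, and a non-empty species set implies identification.
#'
#' @param sample_id,grasshopper_id,mesocosm_id Character/integer vectors.
#' @param occasion Integer sampling occasion (1-4 in the emulated design).
#' @param sample_type `"faecal"` or `"regurgitate"`.
#' @param sex `"female"` or `"male"`.
#' @param amplified,identified Logical vectors.
#' @param species_set List of character vectors (default: empty sets).
#' @return A data frame of class `sample_records`.
#' @export
sample_records <- function(sample_id, grasshopper_id, mesocosm_id, occasion,
                           sample_type, sex, amplified, identified,
                           species_set = NULL) {
  n <- length(sample_id)
  if (is.null(species_set)) species_set <- replicate(n, character(0),
                                                     simplify = FALSE)
  stopifnot(all(sample_type %in% c("faecal", "regurgitate")),
            all(sex %in% c("female", "male")),
            length(species_set) == n)
  if (any(identified & !amplified)) {
    stop("identified samples must have amplified", call. = FALSE)
  }
  nonempty <- vapply(species_set, length, 1L) > 0L
  if (any(nonempty & !identified)) {
    stop("a non-empty species set implies identification", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id,
                    grasshopper_id = grasshopper_id,
                    mesocosm_id = mesocosm_id,
                    occasion = as.integer(occasion),
                    sample_type = sample_type,
                    sex = sex,
                    amplified = amplified,
                    identified = identified,
                    stringsAsFactors = FALSE)
  out$species_set <- species_set
  class(out) <- c("sample_records", class(out))
  out
}

#' Grouped success proportions with Wilson intervals
#'
#' @param records A `sample_records` data frame.
#' @param group_by Grouping: by `sample_type`, by `sex`, `both`, or `none`
#'   (one overall row).
#' @param success Name of a logical column (e.g. `"amplified"`,
#'   `"identified"`) or a predicate function applied to the records.
#' @param conf Confidence level for the Wilson interval.
#' @return Data frame with one row per group: group columns, `n_success`,
#'   `n_total`, `proportion`, `lower`, `upper`, and `undefined` flagging
#'   empty groups.
#' @export
proportion_summary <- function(records,
                               group_by = c("both", "sample_type", "sex",
                                            "none"),
                               success = "amplified",
                               conf = 0.95) {
  group_by <- match.arg(group_by)
  if (nrow(records) == 0L) stop("no records given", call. = FALSE)
  ok <- if (is.function(success)) success(records) else records[[success]]
  if (!is.logical(ok)) stop("success must yield a logical vector",
                            call. = FALSE)
  cols <- switch(group_by,
                 both = c("sample_type", "sex"),
                 sample_type = "sample_type",
                 sex = "sex",
                 none = character(0))
  if (length(cols) == 0L) {
    groups <- factor(rep("all", nrow(records)))
  } else {
    groups <- interaction(records[cols], drop = FALSE, sep = ":")
  }
  lv <- levels(groups)
  rows <- lapply(lv, function(g) {
    idx <- groups == g
    n <- sum(idx)
    s <- sum(ok[idx])
    if (n == 0L) {
      ci <- c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- wilson_ci(s, n, conf)
    }
    data.frame(group = g, n_success = s, n_total = n,
               proportion = ci[["estimate"]],
               lower = ci[["lower"]], upper = ci[["upper"]],
               undefined = n == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(cols) > 0L) {
    parts <- do.call(rbind, strsplit(as.character(out$group), ":", fixed = TRUE))
    for (i in seq_along(cols)) out[[cols[i]]] <- parts[, i]
    out <- out[c(cols, setdiff(names(out), c(cols, "group")))]
  } else {
    out$group <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Relative difference between two proportions
#'
#' The percentage by which `p_a` exceeds `p_b`: `100 * (p_a - p_b) / p_b`.
#' Used to compare group success probabilities (e.g. estimated marginal
#' means) in relative terms.
#'
#' @param p_a,p_b Proportions; `p_b` must be positive.
#' @return List with `percent` (unrounded) and `percent_rounded`
#'   (half-up to the nearest integer, the reporting convention).
#' @export
#' @examples
#' relative_difference(0.773, 0.630)$percent_rounded  # 23
relative_difference <- function(p_a, p_b) {
  if (p_b <= 0) stop("baseline proportion must be positive", call. = FALSE)
  pct <- 100 * (p_a - p_b) / p_b
  list(percent = pct, percent_rounded = round_half_up(pct))
}

#' Pair faecal and regurgitate samples from the same grasshopper and occasion
#'
#' Pairs are formed only when both samples have a non-empty identified
#' species set.
#'
#' @param records A `sample_records` data frame.
#' @return Data frame with `grasshopper_id`, `occasion`, and list columns
#'   `faecal_set`, `regurgitate_set`.
#' @export
pair_samples <- function(records) {
  nonempty <- vapply(records$species_set, length, 1L) > 0L
  rec <- records[nonempty, , drop = FALSE]
  key <- paste(rec$grasshopper_id, rec$occasion, sep = "\r")
  fae <- rec[rec$sample_type == "faecal", , drop = FALSE]
  reg <- rec[rec$sample_type == "regurgitate", , drop = FALSE]
  fkey <- paste(fae$grasshopper_id, fae$occasion, sep = "\r")
  rkey <- paste(reg$grasshopper_id, reg$occasion, sep = "\r")
  common <- intersect(fkey, rkey)
  fi <- match(common, fkey)
  ri <- match(common, rkey)
  out <- data.frame(grasshopper_id = fae$grasshopper_id[fi],
                    occasion = fae$occasion[fi],
                    stringsAsFactors = FALSE)
  out$faecal_set <- fae$species_set[fi]
  out$regurgitate_set <- reg$species_set[ri]
  out
}

#' Agreement between paired faecal and regurgitate identifications
#'
#' A pair matches exactly when the two species sets are equal, and at least
#' partially when they share at least one species (so every exact match is
#' also a partial match).
#'
#' @param pairs Data frame from [pair_samples()] (or with list columns
#'   `faecal_set` and `regurgitate_set`).
#' @return List with `n_pairs`, `exact_count`, `exact_pct`, `partial_count`,
#'   `partial_pct` (percentages half-up to whole percent).
#' @export
paired_match_rates <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) stop("no pairs given", call. = FALSE)
  exact <- mapply(function(a, b) setequal(a, b),
                  pairs$faecal_set, pairs$regurgitate_set)
  partial <- mapply(function(a, b) length(intersect(a, b)) > 0L,
                    pairs$faecal_set, pairs$regurgitate_set)
  list(n_pairs = n,
       exact_count = sum(exact),
       exact_pct = round_half_up(100 * sum(exact) / n),
       partial_count = sum(partial),
       partial_pct = round_half_up(100 * sum(partial) / n))
}

#' Mean number of species identified per sample
#'
#' @param count_distribution Named numeric vector mapping species count to
#'   number of samples, e.g. `c("1" = 335, "2" = 133, "3" = 31, "4" = 1)`.
#' @return List with `mean` (unrounded) and `mean_2dp` (half-up to two
#'   decimals, the reporting convention).
#' @export
mean_species_per_sample <- function(count_distribution) {
  if (length(count_distribution) == 0L) {
    stop("empty count distribution", call. = FALSE)
  }
  k <- as.numeric(names(count_distribution))
  n <- as.numeric(count_distribution)
  if (anyNA(k) || any(k < 1)) {
    stop("species counts must be named integers >= 1", call. = FALSE)
  }
  if (any(n < 0) || sum(n) == 0) {
    stop("sample counts must be non-negative and not all zero",
         call. = FALSE)
  }
  m <- sum(k * n) / sum(n)
  list(mean = m, mean_2dp = round_half_up(m, 2))
}

#' Species-level deviance from the expected faecal identification frequency
#'
#' Each (sample, species) identification is one event; multiple bands
#' pointing at the same species within a sample count once. For every
#' species identified from at least `min_samples` samples, computes the
#' proportion of its identifications that came from faecal samples, a Wilson
#' interval on that proportion, and the deviance (observed minus expected).
#' A species identified from faecal samples more often than the expected
#' frequency has positive deviance.
#'
#' @param records A `sample_records` data frame with identified species sets.
#' @param expected_prop Expected faecal share of identifications; in the
#'   emulated study this is the overall proportion of positive
#'   identifications from faecal samples (0.66). Supplied, not derived.
#' @param min_samples Minimum total identifications for a species to be
#'   retained (default 5).
#' @param conf Confidence level for the Wilson interval.
#' @return Data frame with `species_id`, `n_faecal_ids`, `n_total_ids`,
#'   `observed_prop`, `expected_prop`, `deviance`, `ci_low`, `ci_high`.
#' @export
faecal_deviance_table <- function(records, expected_prop = 0.66,
                                  min_samples = 5L, conf = 0.95) {
  stopifnot(expected_prop >= 0, expected_prop <= 1)
  counts <- vapply(records$species_set, length, 1L)
  if (sum(counts) == 0L) {
    stop("records contain no species identifications", call. = FALSE)
  }
  events <- data.frame(
    species_id = unlist(records$species_set),
    faecal = rep(records$sample_type == "faecal", counts),
    stringsAsFactors = FALSE)
  total <- table(events$species_id)
  faecal <- tapply(events$faecal, events$species_id, sum)
  keep <- names(total)[total >= min_samples]
  rows <- lapply(sort(keep), function(sp) {
    n <- as.integer(total[[sp]])
    x <- as.integer(faecal[[sp]])
    ci <- wilson_ci(x, n, conf)
    data.frame(species_id = sp, n_faecal_ids = x, n_total_ids = n,
               observed_prop = ci[["estimate"]],
               expected_prop = expected_prop,
               deviance = ci[["estimate"]] - expected_prop,
               ci_low = ci[["lower"]], ci_high = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-squared contingency-table test
#'
#' The classical statistic: expected counts from the product of row and
#' column margins, `sum((O - E)^2 / E)` on `(r - 1)(c - 1)` degrees of
#' freedom, with the p-value from the upper tail. No continuity correction.
#'
#' @param tab Matrix (or table) of non-negative counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Simple linear regression of deviance on a species trait
#'
#' Ordinary least squares of a numeric response (typically deviance from
#' expected faecal frequency) on a single predictor, which may be a numeric
#' trait (e.g. specific leaf area) or a binary group code (factor or
#' character with two levels, coded 0/1 in sorted level order).
#'
#' @param response Numeric vector.
#' @param predictor Numeric, factor, or character vector of the same length.
#' @return List with `slope`, `intercept`, `slope_se`, `slope_t`, `slope_p`,
#'   `n`.
#' @export
simple_linear_regression <- function(response, predictor) {
  if (is.character(predictor) || is.factor(predictor)) {
    lv <- sort(unique(as.character(predictor)))
    if (length(lv) != 2L) {
      stop("categorical predictor must have exactly two levels",
           call. = FALSE)
    }
    predictor <- as.numeric(match(as.character(predictor), lv) - 1L)
  }
  ok <- stats::complete.cases(response, predictor)
  response <- response[ok]
  predictor <- predictor[ok]
  n <- length(response)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(predictor) == 0) {
    stop("predictor is constant", call. = FALSE)
  }
  fit <- stats::lm(response ~ predictor)
  sm <- summary(fit)$coefficients
  list(slope = sm["predictor", "Estimate"],
       intercept = sm["(Intercept)", "Estimate"],
       slope_se = sm["predictor", "Std. Error"],
       slope_t = sm["predictor", "t value"],
       slope_p = sm["predictor", "Pr(>|t|)"],
       n = n)
}
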