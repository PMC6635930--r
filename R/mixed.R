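#' Hardy-Weinberg expected counts of sample classes
#'
#' Under panmictic host contact and equal persistence of both parasite
#' species on a shared host, and assuming the two species are equally
#' frequent inside the zone, pure-north : mixed : pure-south samples are
#' expected in 1:2:1 proportions.
#'
#' @param total total number of classified hosts (>= 1).
#' @return Named numeric vector of expected counts
#'   `(pure_north, mixed, pure_south) = total * c(1, 2, 1) / 4`.
#' @examples
#' hw_expected_counts(93)
#' @export
hw_expected_counts <- function(total) {
  if (length(total) != 1 || is.na(total) || total < 1) {
    stop_cd("total must be a positive count")
  }
  c(pure_north = total / 4, mixed = total / 2, pure_south = total / 4)
}

#' Test mixed-sample proportions against 1:2:1
#'
#' Pearson chi-square test (df = 2) of the observed pure-north / mixed /
#' pure-south sample counts against the Hardy-Weinberg 1:2:1 expectation;
#' a deficit of mixed samples indicates non-random species association or
#' rapid within-host replacement. An exact multinomial test is available
#' for small totals.
#'
#' @param observed three non-negative integer counts, in the order
#'   pure-north, mixed, pure-south (names are attached if missing).
#' @param expected_prob expected class probabilities (default `1:2:1`).
#'   Use [zone_adjusted_expectation()] for the per-bin-adjusted variant.
#' @param exact use an exact multinomial test (sum of probabilities of all
#'   outcomes at most as probable as the observed one) instead of the
#'   chi-square approximation.
#' @return An object of class `"htest"` with `statistic` (X-squared),
#'   `parameter` (df), `p.value`, `observed` and `expected` counts.
#' @examples
#' mixed_proportion_test(c(30, 30, 33))
#' @export
mixed_proportion_test <- function(observed, expected_prob = c(1, 2, 1) / 4,
                                  exact = FALSE) {
  if (length(observed) != 3 || anyNA(observed) || any(observed < 0)) {
    stop_cd("observed must be three non-negative counts")
  }
  total <- sum(observed)
  if (total < 1) stop_cd("at least one classified host is required")
  expected_prob <- expected_prob / sum(expected_prob)
  expected <- total * expected_prob
  names(observed) <- names(expected) <- c("pure_north", "mixed", "pure_south")

  if (exact) {
    p_obs <- stats::dmultinom(observed, prob = expected_prob)
    grid <- expand.grid(a = 0:total, b = 0:total)
    grid <- grid[grid$a + grid$b <= total, ]
    probs <- mapply(function(a, b) {
      stats::dmultinom(c(a, b, total - a - b), prob = expected_prob)
    }, grid$a, grid$b)
    p <- sum(probs[probs <= p_obs + 1e-12])
    stat <- sum((observed - expected)^2 / expected)
    method <- "Exact multinomial test against 1:2:1 class proportions"
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(observed, p = expected_prob, correct = FALSE))
    stat <- unname(ct$statistic)
    p <- ct$p.value
    method <- "Pearson chi-square test against 1:2:1 class proportions"
  }
  structure(list(
    statistic = c(`X-squared` = stat),
    parameter = c(df = 2),
    p.value = p,
    method = method,
    data.name = deparse(substitute(observed)),
    observed = observed,
    expected = expected
  ), class = "htest")
}

#' Zone-frequency-adjusted class expectation
#'
#' Optional alternative to the flat 1:2:1 expectation: with local invader
#' frequency `p_i` for host `i`, Hardy-Weinberg class probabilities are
#' `p_i^2`, `2 p_i (1 - p_i)`, `(1 - p_i)^2`; averaging over the hosts'
#' local frequencies gives the expected class proportions for the pooled
#' sample.
#'
#' @param p local invader frequencies of the sampled hosts, in `[0, 1]`.
#' @return Expected class probability vector (pure_north, mixed,
#'   pure_south), summing to one.
#' @export
zone_adjusted_expectation <- function(p) {
  if (any(p < 0 | p > 1)) stop_cd("frequencies must lie in [0, 1]")
  c(pure_north = mean(p^2),
    mixed = mean(2 * p * (1 - p)),
    pure_south = mean((1 - p)^2))
}

#' Probability a finite louse sample reveals a mixed infection
#'
#' A host may carry both species, yet a finite sample of its lice can by
#' chance contain only one. With `n` lice sampled independently and a
#' minority-species frequency `f` on the host, the probability that the
#' sample contains both species is `1 - (1 - f)^n - f^n`.
#'
#' @param n_lice number of lice examined per host (>= 1).
#' @param minority_freq within-host frequency of the rarer species,
#'   strictly inside `(0, 1)`.
#' @return Detection probability in `[0, 1)` (vectorised).
#' @examples
#' detection_probability(40, 0.5)
#' detection_probability(1, 0.3)   # a single louse can never reveal both
#' @export
detection_probability <- function(n_lice, minority_freq) {
  if (any(n_lice < 1)) stop_cd("n_lice must be at least 1")
  if (any(minority_freq <= 0 | minority_freq >= 1)) {
    stop_cd("minority_freq must lie strictly in (0, 1)")
  }
  1 - (1 - minority_freq)^n_lice - minority_freq^n_lice
}

#' Smallest minority frequency detectable at a given miss rate
#'
#' Companion calculator to [detection_probability()]: the minority
#' frequency `f` at which the chance of drawing `n` lice all of the
#' majority species equals `miss_p`, i.e. `(1 - f)^n = miss_p`, so
#' `f = 1 - miss_p^(1/n)`. At `n = 40` and `miss_p = 0.025` this is about
#' 0.088: mixtures rarer than ~9% minority are likely to be missed.
#'
#' @param n_lice lice examined per host.
#' @param miss_p tolerated probability of missing the minority species.
#' @return Minority frequency in `(0, 1)`.
#' @export
min_detectable_freq <- function(n_lice, miss_p) {
  if (any(n_lice < 1)) stop_cd("n_lice must be at least 1")
  if (any(miss_p <= 0 | miss_p >= 1)) stop_cd("miss_p must lie in (0, 1)")
  1 - miss_p^(1 / n_lice)
}

#' Select hosts inside the fitted 0.2-0.8 zone
#'
#' Explicit filter used before [mixed_proportion_test()]: keeps records
#' whose transect position lies within `[x08, x02]` of their survey's
#' fitted metrics, and records the selection provenance.
#'
#' @param records a `"specimen_records"` data.frame.
#' @param metrics a `"zone_metrics"` table with a row for each survey year
#'   present in `records` (matched on `year` rounded to the survey year
#'   when `match_year` is `"nearest"`).
#' @param match_year `"exact"` or `"nearest"`.
#' @return The filtered records with a `"zone_selection"` attribute (a
#'   data.frame of the `year`, `x08`, `x02` bounds used and hosts kept).
#' @export
in_zone_records <- function(records, metrics,
                            match_year = c("nearest", "exact")) {
  match_year <- match.arg(match_year)
  if (!inherits(records, "specimen_records")) {
    records <- suppressMessages(as_specimen_records(records))
  }
  keep <- logical(nrow(records))
  prov <- list()
  for (i in seq_len(nrow(metrics))) {
    yr <- metrics$year[i]
    sel <- if (match_year == "exact") records$year == yr
           else abs(records$year - yr) ==
                  do.call(pmin, lapply(metrics$year,
                                       function(y) abs(records$year - y)))
    inside <- sel & records$position_m >= metrics$x08[i] &
      records$position_m <= metrics$x02[i]
    keep <- keep | inside
    prov[[i]] <- data.frame(year = yr, x08 = metrics$x08[i],
                            x02 = metrics$x02[i], n_kept = sum(inside))
  }
  out <- records[keep, , drop = FALSE]
  message(nrow(out), " of ", nrow(records),
          " record(s) fall inside the 0.2-0.8 zone")
  attr(out, "zone_selection") <- do.call(rbind, prov)
  class(out) <- c("specimen_records", "data.frame")
  out
}
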