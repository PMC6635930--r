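#' Configuration for the synthetic moving-zone survey generator
#'
#' Bundles the parameters of a simulated species-replacement zone: a
#' sigmoidal invader cline translating southward at constant velocity,
#' hosts scattered along the transect at a fixed density each survey,
#' finite per-host louse samples, a tunable deficit of mixed-species hosts
#' relative to Hardy-Weinberg expectations, a leading tail of rare
#' long-distance ("jump") colonists beyond the front and a lagging tail of
#' residual resident-species hosts behind it.
#'
#' Defaults describe a zone advancing at 150 m/year with a 1,000-m
#' 0.2--0.8 width, surveyed in 1991, 1996, 2001 and 2016 at 15 hosts/km
#' over a 0--12,000 m transect, with a mean of 40 lice per host and a
#' mixed-host probability scaled to 0.65 of the Hardy-Weinberg value.
#'
#' @param v zone velocity, m/year (southward positive).
#' @param width_0208 true 0.2--0.8 cline width, meters.
#' @param s asymmetry exponent of the generating curve.
#' @param c0 cline center (50% point) at `t0`, meters.
#' @param t0 reference decimal year for `c0`.
#' @param survey_years decimal years of the surveys.
#' @param transect_span length-2 numeric, transect extent in meters.
#' @param host_density hosts per kilometer per survey.
#' @param lice_mean expected lice examined per host.
#' @param mixed_deficit factor in `[0, 1]` scaling the `2 p (1 - p)`
#'   mixed-host probability; 1 reproduces Hardy-Weinberg proportions.
#' @param minority_range range of the within-host minority-species
#'   fraction for mixed hosts (drawn uniformly).
#' @param jump_rate expected number of jump colonists (pure-invader hosts
#'   beyond the 0.2 point) per survey.
#' @param jump_max maximal jump distance beyond the 0.2 point, meters.
#' @param lag_rate expected number of residual resident hosts north of
#'   the 0.8 point per survey.
#' @param lag_max extent of the lagging tail north of the 0.8 point,
#'   meters.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `"zone_sim_config"` (a validated list).
#' @seealso [simulate_survey()], [true_cline()], [write_fixture()]
#' @export
zone_sim_config <- function(v = 150, width_0208 = 1000, s = 1,
                            c0 = 3400, t0 = 1991,
                            survey_years = c(1991, 1996, 2001, 2016),
                            transect_span = c(0, 12000),
                            host_density = 15, lice_mean = 40,
                            mixed_deficit = 0.65,
                            minority_range = c(0.05, 0.5),
                            jump_rate = 3, jump_max = 2000,
                            lag_rate = 3, lag_max = 1500,
                            seed = 20190614) {
  cfg <- list(v = v, width_0208 = width_0208, s = s, c0 = c0, t0 = t0,
              survey_years = sort(survey_years),
              transect_span = as.numeric(transect_span),
              host_density = host_density, lice_mean = lice_mean,
              mixed_deficit = mixed_deficit,
              minority_range = as.numeric(minority_range),
              jump_rate = jump_rate, jump_max = jump_max,
              lag_rate = lag_rate, lag_max = lag_max,
              seed = as.integer(seed))
  with(cfg, {
    if (v <= 0 || width_0208 <= 0 || host_density <= 0 || lice_mean <= 0) {
      stop_cd("v, width_0208, host_density and lice_mean must be positive")
    }
    if (mixed_deficit < 0 || mixed_deficit > 1) {
      stop_cd("mixed_deficit must lie in [0, 1]")
    }
    if (diff(transect_span) <= 0) stop_cd("transect_span must be increasing")
    if (any(survey_years < 1850 | survey_years > 2100)) {
      stop_cd("survey_years outside the plausible window")
    }
    if (any(survey_years < t0)) {
      stop_cd("survey years must not precede the reference year t0")
    }
  })
  structure(cfg, class = "zone_sim_config")
}

#' True generating cline at a given year
#'
#' The generating curve has asymptotes 0 and 1, its 50% crossing at
#' `c0 + v (year - t0)`, and its decadic slope chosen so that the true
#' 0.2--0.8 width equals `width_0208` exactly; for `s = 1` this reduces to
#' `b = 2 log10(4) / width_0208`.
#'
#' @param config a [zone_sim_config()].
#' @param year decimal year, `>= t0`.
#' @return A [logistic5()] parameter set.
#' @export
true_cline <- function(config, year) {
  stopifnot(inherits(config, "zone_sim_config"))
  if (year < config$t0) stop_cd("year precedes the reference year t0")
  s <- config$s
  center <- config$c0 + config$v * (year - config$t0)
  # width in slope-free units: log10-gap between the 0.2 and 0.8 crossings
  gap <- log10((1 / 0.2)^(1 / s) - 1) - log10((1 / 0.8)^(1 / s) - 1)
  b <- gap / config$width_0208
  # place the 50% crossing (not xmid, which differs when s != 1) at center
  xmid <- center - log10(2^(1 / s) - 1) / b
  logistic5(B = 0, T = 1, b = b, xmid = xmid, s = s)
}

#' Simulate one survey of the moving zone
#'
#' Hosts are placed uniformly along the transect with a Poisson-distributed
#' count at the configured density. Each host's class is drawn from its
#' local invader frequency `p` on the true cline: mixed with probability
#' `mixed_deficit * 2 p (1 - p)`, otherwise pure-invader vs pure-resident
#' with probabilities proportional to `p^2` and `(1 - p)^2`. Louse counts
#' are Poisson with the configured mean (minimum 1; minimum 2 for mixed
#' hosts), and a mixed host's minority species — the locally rarer one —
#' gets a binomial share at a uniformly drawn minority fraction. On top of
#' the cline the generator plants `Poisson(jump_rate)` pure-invader jump
#' colonists uniformly within `(x02, x02 + jump_max]` and
#' `Poisson(lag_rate)` residual resident hosts within
#' `[x08 - lag_max, x08)`, truncated to the transect.
#'
#' The draw is fully reproducible: the RNG substream is derived from
#' `config$seed` and the survey year, and the caller's RNG state is left
#' untouched.
#'
#' @param config a [zone_sim_config()].
#' @param year decimal survey year.
#' @return A `"specimen_records"` data.frame.
#' @examples
#' cfg <- zone_sim_config(seed = 1)
#' rec <- simulate_survey(cfg, 1991)
#' table(rec$sample_class)
#' @export
simulate_survey <- function(config, year) {
  stopifnot(inherits(config, "zone_sim_config"))
  truth <- true_cline(config, year)
  span <- config$transect_span
  span_km <- diff(span) / 1000
  if (span_km <= 0 || config$host_density <= 0) {
    stop_cd("empty transect or zero host density")
  }
  sub_seed <- (config$seed + 97L * as.integer(round(year))) %%
    .Machine$integer.max

  with_seed(sub_seed, {
    n_hosts <- stats::rpois(1, config$host_density * span_km)
    pos <- sort(stats::runif(n_hosts, span[1], span[2]))
    p <- cline_eval(truth, pos)

    pr_mixed <- config$mixed_deficit * 2 * p * (1 - p)
    pure_north_share <- p^2 / (p^2 + (1 - p)^2)
    u <- stats::runif(n_hosts)
    state <- ifelse(u < pr_mixed, "MIXED",
                    ifelse(stats::runif(n_hosts) < pure_north_share,
                           "PURE_NORTH", "PURE_SOUTH"))

    n_lice <- pmax(stats::rpois(n_hosts, config$lice_mean), 1L)
    n_lice[state == "MIXED"] <- pmax(n_lice[state == "MIXED"], 2L)
    n_north <- ifelse(state == "PURE_NORTH", n_lice, 0L)
    n_south <- ifelse(state == "PURE_SOUTH", n_lice, 0L)

    mixed <- which(state == "MIXED")
    if (length(mixed)) {
      fmin <- stats::runif(length(mixed), config$minority_range[1],
                           config$minority_range[2])
      m <- stats::rbinom(length(mixed), n_lice[mixed], fmin)
      m <- pmin(pmax(m, 1L), n_lice[mixed] - 1L)  # both species present
      minority_is_south <- p[mixed] >= 0.5        # rarer species locally
      n_north[mixed] <- ifelse(minority_is_south, n_lice[mixed] - m, m)
      n_south[mixed] <- n_lice[mixed] - n_north[mixed]
    }

    x02 <- invert_cline(truth, 0.2)
    x08 <- invert_cline(truth, 0.8)
    n_jump <- stats::rpois(1, config$jump_rate)
    jump_pos <- stats::runif(n_jump, x02, x02 + config$jump_max)
    jump_pos <- jump_pos[jump_pos >= span[1] & jump_pos <= span[2]]
    n_lag <- stats::rpois(1, config$lag_rate)
    lag_pos <- stats::runif(n_lag, x08 - config$lag_max, x08)
    lag_pos <- lag_pos[lag_pos >= span[1] & lag_pos <= span[2]]

    tail_lice <- pmax(stats::rpois(length(jump_pos) + length(lag_pos),
                                   config$lice_mean), 1L)
    pos <- c(pos, jump_pos, lag_pos)
    n_north <- c(n_north, tail_lice[seq_along(jump_pos)],
                 rep(0L, length(lag_pos)))
    n_south <- c(n_south, rep(0L, length(jump_pos)),
                 tail_lice[length(jump_pos) + seq_along(lag_pos)])

    o <- order(pos)
    df <- data.frame(
      host_id = sprintf("Y%d_H%03d", round(year), seq_along(pos)),
      year = year,
      position_m = pos[o],
      n_north = as.integer(n_north[o]),
      n_south = as.integer(n_south[o]),
      stringsAsFactors = FALSE
    )
    df$sample_class <- classify_sample(df$n_north, df$n_south)
    class(df) <- c("specimen_records", "data.frame")
    df
  })
}

#' Simulate every configured survey
#'
#' @param config a [zone_sim_config()].
#' @return Named list of `"specimen_records"`, one per survey year.
#' @export
simulate_zone <- function(config) {
  stopifnot(inherits(config, "zone_sim_config"))
  recs <- lapply(config$survey_years, function(y) simulate_survey(config, y))
  stats::setNames(recs, as.character(config$survey_years))
}

#' Write a synthetic survey fixture to disk
#'
#' Writes one `survey_<year>.csv` per configured survey plus a
#' `manifest.json` recording the configuration and the true per-year cline
#' parameters and metric positions, so recovery tests can compare pipeline
#' estimates against the generating truth.
#'
#' @param config a [zone_sim_config()].
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(config, dir) {
  stopifnot(inherits(config, "zone_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- simulate_zone(config)
  files <- list()
  truth <- list()
  for (y in names(recs)) {
    f <- file.path(dir, paste0("survey_", y, ".csv"))
    write_survey(recs[[y]], f)
    files[[y]] <- list(file = basename(f), n_records = nrow(recs[[y]]))
    tc <- true_cline(config, as.numeric(y))
    truth[[y]] <- list(params = as.list(unclass(tc)),
                       x08 = invert_cline(tc, 0.8),
                       ip = invert_cline(tc, 0.5),
                       x02 = invert_cline(tc, 0.2),
                       width_0208 = config$width_0208)
  }
  manifest <- list(config = unclass(config), surveys = files,
                   true_metrics = truth)
  write_json_report(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}
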