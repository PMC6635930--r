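#' Average annual rate of movement between two surveys
#'
#' @param pos_a,pos_b metric positions in meters at the two surveys.
#' @param year_a,year_b decimal survey years, `year_b > year_a`.
#' @return Rate in m/year; negative values mean northward retreat.
#' @examples
#' interval_rate(3420, 7026, 1991, 2016)  # 144.24 m/year southward
#' @export
interval_rate <- function(pos_a, pos_b, year_a, year_b) {
  if (any(year_b <= year_a)) {
    stop_cd("year_b must exceed year_a (zero or negative interval)")
  }
  (pos_b - pos_a) / (year_b - year_a)
}

#' Interval rates of zone movement for a metrics table
#'
#' Computes, for each consecutive pair of surveys and for the full span,
#' the average annual rate of movement of each positional zone metric —
#' the analogue of a published interval-rate table.
#'
#' @param metrics a `"zone_metrics"` data.frame (one row per survey).
#' @param metrics_names which positional metrics to include.
#' @param digits rounding for the returned rates; `NA` for unrounded.
#' @return A data.frame with columns `interval`, `years` and one rate
#'   column per metric (m/year).
#' @examples
#' tab <- zone_metrics_table(
#'   zone_metrics_row(1991, 2300, 2492, 3420, 3760, 3900),
#'   zone_metrics_row(2016, 4900, 6558, 7026, 7516, 9700))
#' drift_table(tab)
#' @export
drift_table <- function(metrics,
                        metrics_names = c("nGc", "x08", "ip", "x02", "sGa"),
                        digits = NA) {
  metrics <- metrics[order(metrics$year), , drop = FALSE]
  if (nrow(metrics) < 2) stop_cd("need at least two surveys for rates")
  pairs <- cbind(seq_len(nrow(metrics) - 1), seq_len(nrow(metrics) - 1) + 1)
  if (nrow(metrics) > 2) pairs <- rbind(pairs, c(1, nrow(metrics)))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    rates <- vapply(metrics_names, function(m) {
      interval_rate(metrics[[m]][a], metrics[[m]][b],
                    metrics$year[a], metrics$year[b])
    }, numeric(1))
    if (!is.na(digits)) rates <- round(rates, digits)
    data.frame(interval = paste0(metrics$year[a], "-", metrics$year[b]),
               years = metrics$year[b] - metrics$year[a],
               as.list(rates))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear trend of a zone metric over survey years
#'
#' Ordinary least-squares regression of metric position (m) on survey year
#' with the one-tailed test appropriate for a directional southward-advance
#' hypothesis: the null is no linear association (`r = 0`), the alternative
#' is a positive association (`r > 0`), tested with
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' The x-intercept year — the year the line crosses position 0, i.e. the
#' extrapolated arrival of the front at the transect origin — is
#' `-intercept / slope`.
#'
#' @param year decimal survey years (strictly increasing), or a
#'   two-column data.frame/list with `year` and `position`.
#' @param position metric positions in meters.
#' @param metric_name optional label carried in the result.
#' @param two_tailed report the two-tailed p-value instead of the
#'   directional one-tailed test.
#' @return An object of class `"trend_fit"`: list with `slope` (m/year),
#'   `intercept` (m at year 0), `r`, `t_stat`, `df`, `p` (one-tailed
#'   unless `two_tailed`), `n`, `x_intercept_year` and `metric_name`.
#'   With `n = 2` the slope is exact and `p` is `NA`.
#' @examples
#' fit_trend(c(1991, 1996, 2001, 2016), c(3420, 4231, 4547, 7026))
#' @export
fit_trend <- function(year, position = NULL, metric_name = NA_character_,
                      two_tailed = FALSE) {
  if (is.null(position)) {
    position <- year$position
    year <- year$year
  }
  if (length(year) != length(position) || length(year) < 2) {
    stop_cd("need at least two (year, position) points")
  }
  if (anyDuplicated(year)) stop_cd("years must be distinct")
  if (stats::sd(year) == 0) stop_cd("years are constant; no trend defined")
  n <- length(year)
  fit <- stats::lm(position ~ year)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (n >= 3 && stats::sd(position) > 0) {
    r <- stats::cor(year, position)
    t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- if (two_tailed) 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
         else stats::pt(t_stat, n - 2, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)  # collinear points: report machine floor
  } else if (n >= 3) {
    r <- 0; t_stat <- 0
    p <- if (two_tailed) 1 else 0.5
  } else {
    r <- NA_real_; t_stat <- NA_real_; p <- NA_real_
  }
  structure(list(
    metric_name = metric_name,
    slope = slope,
    intercept = intercept,
    r = r,
    t_stat = t_stat,
    df = max(n - 2L, 0L),
    p = p,
    two_tailed = two_tailed,
    n = n,
    x_intercept_year = if (slope != 0) -intercept / slope else NA_real_,
    data = data.frame(year = year, position = position)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  lab <- if (is.na(x$metric_name)) "zone metric" else x$metric_name
  cat(sprintf("Trend of %s: %.2f m/year over %d surveys\n",
              lab, x$slope, x$n))
  if (!is.na(x$p)) {
    cat(sprintf("  r = %.3f, t = %.3f (df = %d), %s p = %.4g\n",
                x$r, x$t_stat, x$df,
                if (x$two_tailed) "two-tailed" else "one-tailed", x$p))
  }
  if (!is.na(x$x_intercept_year)) {
    cat(sprintf("  crosses position 0 in year %.1f\n", x$x_intercept_year))
  }
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  year <- if (is.null(newdata)) object$data$year
          else if (is.data.frame(newdata)) newdata$year else newdata
  object$intercept + object$slope * year
}

#' Year at which a trend line crosses position zero
#'
#' For a southward-advancing metric, the x-intercept year dates the
#' arrival of that feature at the transect origin.
#'
#' @param trend a `"trend_fit"`.
#' @return Decimal year.
#' @export
x_intercept_year <- function(trend) {
  stopifnot(inherits(trend, "trend_fit"))
  if (is.na(trend$slope) || trend$slope <= 0) {
    stop_cd("no southward trend: slope must be positive to date an arrival")
  }
  -trend$intercept / trend$slope
}

#' Average arrival year across metric trends
#'
#' Mean and sample standard deviation of the x-intercept years of several
#' metric trends — the aggregate estimate of when the zone front arrived
#' at the transect origin.
#'
#' @param trends list of `"trend_fit"` objects (each with positive slope).
#' @return Named vector `c(mean_year =, sd_years =, n =)`.
#' @export
aggregate_arrival <- function(trends) {
  if (inherits(trends, "trend_fit")) trends <- list(trends)
  if (length(trends) < 2) stop_cd("need at least two trends to aggregate")
  yrs <- vapply(trends, x_intercept_year, numeric(1))
  c(mean_year = mean(yrs), sd_years = stats::sd(yrs), n = length(yrs))
}

#' Travel time of a front over a distance
#'
#' @param distance_m distance in meters (non-negative).
#' @param rate_m_per_year advance rate in m/year (positive).
#' @return Time in years (unrounded).
#' @examples
#' travel_time(9700, 232)  # 41.81 years
#' @export
travel_time <- function(distance_m, rate_m_per_year) {
  if (any(rate_m_per_year <= 0)) stop_cd("rate must be positive")
  if (any(distance_m < 0)) stop_cd("distance must be non-negative")
  distance_m / rate_m_per_year
}

#' Host dispersal distances read off zone metrics
#'
#' The advance rate of the 0.2--0.8 replacement zone tracks the average
#' annual dispersal distance of the hosts (diffusion dispersal), while the
#' advance of the invader's southernmost record tracks the maximum annual
#' dispersal distance (jump dispersal). Both are estimated as regression
#' slopes of the corresponding metrics on survey year.
#'
#' @param metrics a `"zone_metrics"` data.frame with at least two surveys.
#' @return List with `mean_annual` (mean of the x08/ip/x02 trend slopes,
#'   m/year), `sd_annual` (their sample SD), `max_annual` (the sGa trend
#'   slope) and the underlying `trends`.
#' @export
dispersal_estimates <- function(metrics) {
  if (nrow(metrics) < 2) stop_cd("need at least two surveys")
  core <- c("x08", "ip", "x02")
  trends <- lapply(c(core, "sGa"), function(m) {
    fit_trend(metrics$year, metrics[[m]], metric_name = m)
  })
  names(trends) <- c(core, "sGa")
  slopes <- vapply(trends[core], `[[`, numeric(1), "slope")
  list(mean_annual = mean(slopes),
       sd_annual = stats::sd(slopes),
       max_annual = trends[["sGa"]]$slope,
       trends = trends)
}

#' Fit trends for all positional metrics of a table
#'
#' @param metrics a `"zone_metrics"` data.frame.
#' @param metrics_names metrics to regress on year.
#' @param two_tailed passed to [fit_trend()].
#' @return Named list of `"trend_fit"` objects.
#' @export
metric_trends <- function(metrics,
                          metrics_names = c("nGc", "x08", "ip", "x02", "sGa"),
                          two_tailed = FALSE) {
  out <- lapply(metrics_names, function(m) {
    fit_trend(metrics$year, metrics[[m]], metric_name = m,
              two_tailed = two_tailed)
  })
  stats::setNames(out, metrics_names)
}
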