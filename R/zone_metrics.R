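#' Range extremes of the two species in a survey
#'
#' The raw-record extremes bounding the full replacement zone: the
#' northernmost occurrence of the southern (resident) species and the
#' southernmost occurrence of the northern (invading) species. A
#' mixed-species host contains both species and therefore counts for both
#' extremes. An extreme is `NA` when the species is absent from the survey.
#'
#' @param records a `"specimen_records"` data.frame.
#' @return Named numeric vector `c(nGc =, sGa =)`: the minimum position
#'   with any southern lice and the maximum position with any northern
#'   lice, in meters.
#' @export
extreme_positions <- function(records) {
  if (!inherits(records, "specimen_records")) {
    records <- suppressMessages(as_specimen_records(records))
  }
  has_south <- records$n_south >= 1
  has_north <- records$n_north >= 1
  c(nGc = if (any(has_south)) min(records$position_m[has_south]) else NA_real_,
    sGa = if (any(has_north)) max(records$position_m[has_north]) else NA_real_)
}

#' Zone metrics for one survey
#'
#' Computes the standard per-survey description of a replacement zone from
#' a fitted cline plus the raw records: the fitted 80%, 50% and 20%
#' invader-frequency positions (`x08`, `ip`, `x02`), the raw range
#' extremes (`nGc`, `sGa`), the full width (`sGa - nGc`) and the
#' conventional 0.2--0.8 cline width (`x02 - x08`), together with the
#' fit's goodness-of-fit values. The positional metrics come from the
#' fitted curve; the extremes are literal host positions, because the
#' leading-edge extreme measures jump dispersal beyond the fitted front.
#'
#' The 50% point is reported as the 50% crossing of the fitted curve; for
#' an asymmetric curve (`s != 1`) this is not the mathematical inflection,
#' which is also available via `inflection = TRUE`.
#'
#' @param fit a converged `"cline_fit"`.
#' @param records the survey's `"specimen_records"` (optional; extremes
#'   and full width are `NA` when omitted).
#' @param year decimal calendar year of the survey.
#' @param inflection also report the mathematical inflection point of the
#'   asymmetric curve as `ip_inflection`.
#' @return An object of class `"zone_metrics"`: a one-row data.frame with
#'   columns `year`, `nGc`, `x08`, `ip`, `x02`, `sGa`, `full_width`,
#'   `width_0208`, `gof`, `weighted_gof`.
#' @examples
#' truth <- logistic5(b = 2 * log10(4) / 1000, xmid = 3400, s = 1)
#' x <- seq(200, 7800, by = 400)
#' fit <- fit_cline(x, cline_eval(truth, x))
#' zone_metrics(fit, year = 1991)
#' @seealso [zone_metrics_row()] for printed tables without a fit,
#'   [drift_table()] for rates of movement across surveys.
#' @export
zone_metrics <- function(fit, records = NULL, year, inflection = FALSE) {
  stopifnot(inherits(fit, "cline_fit"))
  if (!fit$converged) stop_cd("cline fit did not converge; refusing metrics")
  pos <- vapply(c(x08 = 0.8, ip = 0.5, x02 = 0.2), function(y) {
    tryCatch(invert_cline(fit$params, y), clinedrift_domain_error =
               function(e) stop_cd("frequency point ", y,
                                   " outside the fitted asymptotes: ",
                                   conditionMessage(e)))
  }, numeric(1))

  ext <- if (is.null(records)) c(nGc = NA_real_, sGa = NA_real_) else
    extreme_positions(records)
  if (!is.na(ext[["nGc"]]) && ext[["nGc"]] > pos[["x08"]]) {
    warning("northernmost resident record lies south of the fitted 0.8 ",
            "point", call. = FALSE)
  }
  if (!is.na(ext[["sGa"]]) && ext[["sGa"]] < pos[["x02"]]) {
    warning("southernmost invader record lies north of the fitted 0.2 ",
            "point", call. = FALSE)
  }

  out <- data.frame(year = year,
                    nGc = ext[["nGc"]],
                    x08 = pos[["x08"]],
                    ip = pos[["ip"]],
                    x02 = pos[["x02"]],
                    sGa = ext[["sGa"]],
                    full_width = ext[["sGa"]] - ext[["nGc"]],
                    width_0208 = pos[["x02"]] - pos[["x08"]],
                    gof = fit$gof,
                    weighted_gof = fit$weighted_gof)
  if (inflection) {
    # inflection of the 5PL in x: where the second derivative vanishes,
    # 10^(b (x - xmid)) = 1/s
    out$ip_inflection <- fit$params[["xmid"]] -
      log10(fit$params[["s"]]) / fit$params[["b"]]
  }
  class(out) <- c("zone_metrics", "data.frame")
  out
}

#' Assemble a zone-metrics row from known positions
#'
#' Builds a `"zone_metrics"` row directly from positional values — e.g. a
#' published table of per-survey metrics — so the drift-inference stage
#' can run without refitting clines or access to raw records. Widths are
#' derived from the positions.
#'
#' @param year decimal calendar year.
#' @param nGc,x08,ip,x02,sGa positions in meters (see [zone_metrics()]).
#' @param gof,weighted_gof optional fit diagnostics.
#' @return A `"zone_metrics"` one-row data.frame.
#' @examples
#' zone_metrics_row(1991, nGc = 2300, x08 = 2492, ip = 3420,
#'                  x02 = 3760, sGa = 3900)
#' @export
zone_metrics_row <- function(year, nGc = NA_real_, x08, ip, x02,
                             sGa = NA_real_, gof = NA_real_,
                             weighted_gof = NA_real_) {
  if (!(x08 <= ip && ip <= x02)) {
    stop_cd("positions must be ordered x08 <= ip <= x02 for a decreasing ",
            "cline")
  }
  out <- data.frame(year = year, nGc = nGc, x08 = x08, ip = ip, x02 = x02,
                    sGa = sGa, full_width = sGa - nGc,
                    width_0208 = x02 - x08, gof = gof,
                    weighted_gof = weighted_gof)
  class(out) <- c("zone_metrics", "data.frame")
  out
}

#' Bind per-survey zone metrics into a table
#'
#' @param ... `"zone_metrics"` rows (or a single list of them).
#' @return A `"zone_metrics"` data.frame ordered by year, one row per
#'   survey.
#' @export
zone_metrics_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 1 && is.list(rows[[1]]) && !is.data.frame(rows[[1]])) {
    rows <- rows[[1]]
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("zone_metrics", "data.frame")
  out
}

#' @export
print.zone_metrics <- function(x, digits = 1, ...) {
  cat("Replacement-zone metrics (positions in m along the transect):\n")
  print.data.frame(round_df(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
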