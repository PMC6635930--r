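#' Fit a five-parameter logistic cline to binned frequencies
#'
#' Estimates the parameters of the decreasing five-parameter logistic
#' curve (see [logistic5()]) from per-bin invader frequencies by bounded
#' nonlinear least squares. Optimisation uses [stats::nlminb()] under box
#' constraints with a fixed, deterministic multistart grid over the slope,
#' asymmetry and location parameters, so two runs on identical inputs give
#' bit-identical estimates.
#'
#' When the observed frequencies do not span both tails of the curve (or
#' there are too few bins to support five free parameters) the asymptotes
#' are fixed at `B = 0`, `T = 1` and only `(b, xmid, s)` are estimated;
#' `fix_asymptotes = "auto"` (the default) makes that call from the data.
#'
#' @param x bin positions in meters (typically bin midpoints), or a
#'   data.frame from [bin_frequencies()] with columns `x_center_m`,
#'   `freq_north` and optionally `n_hosts`.
#' @param freq observed invader frequencies in `[0, 1]` (ignored when `x`
#'   is a data.frame).
#' @param weights optional non-negative least-squares weights (e.g. hosts
#'   per bin). When `x` is a data.frame the default is unweighted; pass
#'   `weights = "n_hosts"` to weight by bin occupancy.
#' @param fix_asymptotes `"auto"`, `"yes"` or `"no"`.
#' @param constraints named list overriding the default box constraints
#'   `B` in `[0, 0.4]`, `T` in `[0.6, 1]`, `b` in `(0, 0.1]` per meter,
#'   `s` in `[0.1, 10]`, `xmid` within the data range extended by half its
#'   span.
#' @param weight_exponent exponent used by the weighted goodness-of-fit
#'   (see [goodness_of_fit()]).
#' @return An object of class `"cline_fit"`: a list with elements
#'   `params` ([logistic5()]), `data` (x, freq, weights), `fitted`,
#'   `residuals` (observed minus fitted), `sse`, `gof`, `weighted_gof`,
#'   `n_bins`, `converged`, `fixed_asymptotes` and `optim` diagnostics.
#' @examples
#' truth <- logistic5(b = 2 * log10(4) / 1000, xmid = 3400, s = 1)
#' x <- seq(500, 7500, by = 500)
#' fit <- fit_cline(x, cline_eval(truth, x))
#' coef(fit)
#' predict(fit, newdata = c(2000, 3400, 5000))
#' @seealso [zone_metrics()], [invert_cline()]
#' @export
fit_cline <- function(x, freq = NULL, weights = NULL,
                      fix_asymptotes = c("auto", "yes", "no"),
                      constraints = list(), weight_exponent = 2) {
  fix_asymptotes <- match.arg(fix_asymptotes)
  if (is.data.frame(x)) {
    df <- x
    if (!all(c("x_center_m", "freq_north") %in% names(df))) {
      stop_cd("data.frame input needs columns x_center_m and freq_north")
    }
    if (identical(weights, "n_hosts")) weights <- df$n_hosts
    freq <- df$freq_north
    x <- df$x_center_m
  }
  if (length(x) != length(freq)) stop_cd("x and freq lengths differ")
  keep <- is.finite(x) & is.finite(freq)
  x <- x[keep]; freq <- freq[keep]
  n <- length(x)
  if (any(freq < 0 | freq > 1)) stop_cd("frequencies must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[keep]
  if (length(weights) != n || any(weights < 0)) {
    stop_cd("weights must be non-negative and match the number of bins")
  }
  if (diff(range(freq)) < sqrt(.Machine$double.eps)) {
    stop_cd("all frequencies identical: no cline is identifiable",
            class = "clinedrift_degenerate_error")
  }

  spans_tails <- min(freq) <= 0.2 && max(freq) >= 0.8
  fix_bt <- switch(fix_asymptotes,
                   yes = TRUE, no = FALSE,
                   auto = n < 8 || !spans_tails)
  n_free <- if (fix_bt) 3L else 5L
  if (n < n_free) {
    stop_cd("need at least ", n_free, " bins to estimate ", n_free,
            " free parameters; got ", n)
  }

  span <- diff(range(x))
  if (span <= 0) stop_cd("bin positions are all identical")
  box <- list(B = c(0, 0.4), T = c(0.6, 1), b = c(1e-6, 0.1),
              s = c(0.1, 10),
              xmid = c(min(x) - span / 2, max(x) + span / 2))
  box[names(constraints)] <- constraints

  # order of observations must not matter
  o <- order(x)
  x <- x[o]; freq <- freq[o]; weights <- weights[o]

  sse_fun <- function(p) {
    f <- p[["B"]] + (p[["T"]] - p[["B"]]) /
      (1 + 10^(p[["b"]] * (x - p[["xmid"]])))^p[["s"]]
    sum(weights * (freq - f)^2)
  }

  # fixed 3x3x3 multistart over (b, s, xmid); B, T always start at 0, 1
  b0 <- 2 * log10(4) / (span * c(0.1, 0.3, 0.8))
  b0 <- pmin(pmax(b0, box$b[1]), box$b[2])
  s0 <- c(0.5, 1, 2)
  x0 <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  starts <- expand.grid(b = b0, s = s0, xmid = x0, KEEP.OUT.ATTRS = FALSE)

  par_names <- if (fix_bt) c("b", "xmid", "s") else c("B", "T", "b", "xmid", "s")
  lower <- vapply(box[par_names], `[`, numeric(1), 1)
  upper <- vapply(box[par_names], `[`, numeric(1), 2)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- c(B = 0, T = 1, b = starts$b[i], xmid = starts$xmid[i],
            s = starts$s[i])[par_names]
    st <- pmin(pmax(st, lower), upper)
    obj <- function(p) {
      full <- c(B = 0, T = 1, p[par_names])[c("B", "T", "b", "xmid", "s")]
      if (!fix_bt) full[c("B", "T")] <- p[c("B", "T")]
      sse_fun(full)
    }
    res <- tryCatch(
      stats::nlminb(st, obj, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
  }
  if (is.null(best)) {
    stop_cd("cline optimisation failed from every start")
  }

  p <- c(B = 0, T = 1, best$par[par_names])[c("B", "T", "b", "xmid", "s")]
  if (!fix_bt) p[c("B", "T")] <- best$par[c("B", "T")]
  converged <- isTRUE(best$convergence == 0)
  params <- logistic5(B = p[["B"]], T = p[["T"]], b = max(p[["b"]], 1e-12),
                      xmid = p[["xmid"]], s = p[["s"]])
  fitted <- cline_eval(params, x)
  resid <- freq - fitted
  gof <- goodness_of_fit(freq, fitted, weight_exponent = weight_exponent)

  structure(list(
    params = params,
    data = data.frame(x = x, freq = freq, weights = weights),
    fitted = fitted,
    residuals = resid,
    sse = sum(weights * resid^2),
    gof = gof[["gof"]],
    weighted_gof = gof[["weighted_gof"]],
    n_bins = n,
    converged = converged,
    fixed_asymptotes = fix_bt,
    optim = list(objective = best$objective, convergence = best$convergence,
                 message = best$message %||% "", iterations = best$iterations,
                 n_starts = nrow(starts))
  ), class = "cline_fit")
}

#' Goodness of fit for a cline fit
#'
#' Pseudo-R-squared on the bin frequencies: `gof = 1 - SSE/SST`. The
#' weighted variant down-weights large residuals with weights
#' `w_i = 1 / |r_i|^p` (default `p = 2`), renormalised to sum to one, and
#' applies the same decomposition with those weights, so poorly fitted
#' bins contribute less; it is bounded above by 1 and typically exceeds
#' the unweighted value.
#'
#' @param observed,fitted frequency vectors, or pass a `"cline_fit"` as
#'   `observed` and leave `fitted` missing.
#' @param weight_exponent positive exponent `p`.
#' @return Named numeric vector `c(gof =, weighted_gof =)`.
#' @export
goodness_of_fit <- function(observed, fitted = NULL, weight_exponent = 2) {
  if (inherits(observed, "cline_fit")) {
    fitted <- observed$fitted
    observed <- observed$data$freq
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst < .Machine$double.eps) {
    stop_cd("total sum of squares is zero: goodness of fit undefined")
  }
  r <- observed - fitted
  gof <- 1 - sum(r^2) / sst
  w <- 1 / pmax(abs(r), 1e-8)^weight_exponent
  w <- w / sum(w)
  ybar_w <- sum(w * observed)
  sst_w <- sum(w * (observed - ybar_w)^2)
  wgof <- if (sst_w < .Machine$double.eps) 1 else 1 - sum(w * r^2) / sst_w
  c(gof = gof, weighted_gof = wgof)
}

#' @export
print.cline_fit <- function(x, digits = 4, ...) {
  cat("Five-parameter logistic cline fit\n")
  cat("  bins:", x$n_bins,
      if (x$fixed_asymptotes) " (asymptotes fixed at 0 and 1)" else "", "\n")
  cat("  parameters:\n")
  print(round(unclass(x$params), 6))
  cat(sprintf("  SSE %.6g | GOF %.4f | weighted GOF %.4f | converged: %s\n",
              x$sse, x$gof, x$weighted_gof, x$converged))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...) unclass(object$params)

#' @export
residuals.cline_fit <- function(object, ...) object$residuals

#' @export
fitted.cline_fit <- function(object, ...) object$fitted

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x_center_m %||% newdata$x
       else newdata
  cline_eval(object$params, x)
}

#' @export
summary.cline_fit <- function(object, ...) {
  out <- list(
    params = unclass(object$params),
    n_bins = object$n_bins,
    sse = object$sse,
    gof = object$gof,
    weighted_gof = object$weighted_gof,
    converged = object$converged,
    fixed_asymptotes = object$fixed_asymptotes,
    frequency_points = tryCatch(
      c(x08 = invert_cline(object$params, 0.8),
        ip = invert_cline(object$params, 0.5),
        x02 = invert_cline(object$params, 0.2)),
      error = function(e) NULL),
    residual_range = range(object$residuals)
  )
  class(out) <- "summary.cline_fit"
  out
}

#' @export
print.summary.cline_fit <- function(x, ...) {
  cat("Five-parameter logistic cline fit (", x$n_bins, " bins)\n", sep = "")
  print(round(x$params, 6))
  if (!is.null(x$frequency_points)) {
    cat("frequency points (m): 0.8 at", round(x$frequency_points[["x08"]]),
        "| 0.5 at", round(x$frequency_points[["ip"]]),
        "| 0.2 at", round(x$frequency_points[["x02"]]), "\n")
  }
  cat(sprintf("GOF %.4f, weighted GOF %.4f; converged: %s\n",
              x$gof, x$weighted_gof, x$converged))
  invisible(x)
}

#' Plot a fitted cline
#'
#' Plots the binned frequencies and the fitted curve, marking the
#' conventional 0.2 and 0.8 frequency points when they exist.
#'
#' @param x a `"cline_fit"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cline_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$freq, xlab = "Position along transect (m)",
                 ylab = "Invader frequency", ylim = c(0, 1), pch = 19, ...)
  xs <- seq(min(d$x), max(d$x), length.out = 256)
  graphics::lines(xs, cline_eval(x$params, xs), col = "steelblue", lwd = 2)
  pts <- tryCatch(invert_cline(x$params, c(0.8, 0.2)),
                  error = function(e) NULL)
  if (!is.null(pts)) {
    graphics::abline(v = pts, lty = 3, col = "grey40")
    graphics::axis(3, at = pts, labels = c("0.8", "0.2"), tick = FALSE,
                   line = -1, cex.axis = 0.8)
  }
  invisible(x)
}
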