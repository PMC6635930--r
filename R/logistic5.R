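#' Five-parameter asymmetric logistic cline
#'
#' Constructs the parameter set of the five-parameter logistic (5PL) curve
#' used to describe a geographic frequency cline that decreases southward:
#' \deqn{f(x) = B + \frac{T - B}{\left(1 + 10^{\,b (x - x_{mid})}\right)^{s}}}
#' where `B` and `T` are the lower and upper asymptotes (frequencies), `b`
#' is a decadic slope per meter, `xmid` a location parameter in meters, and
#' `s > 0` an asymmetry exponent. With `s = 1` the curve reduces to the
#' symmetric four-parameter logistic and the 50% frequency point sits at
#' `xmid` exactly; `s != 1` skews the approach to the two asymptotes.
#'
#' @param B lower asymptote, in `[0, 1)` and below `T`.
#' @param T upper asymptote, in `(0, 1]`.
#' @param b decadic slope, per meter; must be positive (frequency decreases
#'   with increasing `x`, i.e. southward for a south-positive transect).
#' @param xmid location parameter, meters.
#' @param s asymmetry exponent, positive.
#' @return An object of class `"logistic5"`: a named numeric vector with a
#'   validated parameter set.
#' @examples
#' p <- logistic5(B = 0, T = 1, b = 0.0012, xmid = 3400, s = 1)
#' cline_eval(p, 3400)      # 0.5 at the midpoint when s = 1
#' invert_cline(p, 0.5)     # 3400
#' @seealso [cline_eval()], [invert_cline()], [fit_cline()]
#' @export
logistic5 <- function(B = 0, T = 1, b, xmid, s = 1) {
  par <- c(B = as.numeric(B), T = as.numeric(T), b = as.numeric(b),
           xmid = as.numeric(xmid), s = as.numeric(s))
  if (anyNA(par) || any(!is.finite(par))) {
    stop_cd("logistic5 parameters must be finite numbers")
  }
  if (!(par["B"] >= 0 && par["B"] < par["T"] && par["T"] <= 1)) {
    stop_cd("asymptotes must satisfy 0 <= B < T <= 1 (got B = ",
            par["B"], ", T = ", par["T"], ")")
  }
  if (par["b"] <= 0) stop_cd("slope b must be positive (decreasing cline)")
  if (par["s"] <= 0) stop_cd("asymmetry s must be positive")
  structure(par, class = "logistic5")
}

#' Evaluate a five-parameter logistic cline
#'
#' @param params a [logistic5()] parameter set.
#' @param x positions in meters (vectorised).
#' @return Frequencies in `[B, T]`, strictly decreasing in `x`.
#' @export
cline_eval <- function(params, x) {
  stopifnot(inherits(params, "logistic5"))
  B <- params[["B"]]; Tt <- params[["T"]]
  b <- params[["b"]]; xmid <- params[["xmid"]]; s <- params[["s"]]
  # 10^(b*(x-xmid)) overflows harmlessly to Inf; the quotient then -> B
  B + (Tt - B) / (1 + 10^(b * (x - xmid)))^s
}

#' Invert a five-parameter logistic cline (closed form)
#'
#' Solves `cline_eval(params, x) = y` for `x`. Used to place the
#' conventional 0.2, 0.5 and 0.8 frequency points of a cline:
#' \deqn{x = x_{mid} + \frac{1}{b}\log_{10}\!\left(\left(\frac{T-B}{y-B}\right)^{1/s} - 1\right)}
#'
#' @param params a [logistic5()] parameter set.
#' @param y target frequencies, strictly inside `(B, T)` (vectorised).
#' @return Positions in meters.
#' @examples
#' p <- logistic5(b = 0.0012, xmid = 3400, s = 1)
#' invert_cline(p, c(0.8, 0.5, 0.2))
#' @export
invert_cline <- function(params, y) {
  stopifnot(inherits(params, "logistic5"))
  B <- params[["B"]]; Tt <- params[["T"]]
  if (any(y <= B | y >= Tt)) {
    stop_cd("target frequency must lie strictly between the asymptotes (",
            B, ", ", Tt, ")", class = "clinedrift_domain_error")
  }
  params[["xmid"]] +
    log10(((Tt - B) / (y - B))^(1 / params[["s"]]) - 1) / params[["b"]]
}

#' @export
print.logistic5 <- function(x, digits = 4, ...) {
  cat("Five-parameter logistic cline (decreasing):\n")
  print(round(unclass(x), digits))
  if (x[["B"]] < 0.5 && x[["T"]] > 0.5) {
    cat("50% crossing at x =", format(invert_cline(x, 0.5), digits = 7), "m\n")
  }
  invisible(x)
}

#' Natural-log slope of a decadic logistic
#'
#' Convenience conversion: the model's decadic exponent `10^(b (x - xmid))`
#' equals `exp(b * ln(10) * (x - xmid))`, so the natural-log slope is
#' `b * log(10)`.
#'
#' @param params a [logistic5()] parameter set.
#' @return Slope per meter on the natural-log scale.
#' @export
natural_slope <- function(params) {
  stopifnot(inherits(params, "logistic5"))
  params[["b"]] * log(10)
}
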