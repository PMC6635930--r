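test_that("the 5PL evaluates to its landmark values", {
  p <- logistic5(B = 0, T = 1, b = 0.001, xmid = 5000, s = 1)
  expect_equal(cline_eval(p, 5000), 0.5)
  expect_equal(cline_eval(p, 1e9), 0)        # lower asymptote
  expect_equal(cline_eval(p, -1e9), 1)       # upper asymptote
  p2 <- logistic5(B = 0, T = 1, b = 0.001, xmid = 5000, s = 2)
  expect_equal(cline_eval(p2, 5000), 0.25)   # (1 + 10^0)^-s
  # strictly decreasing
  x <- seq(0, 10000, by = 100)
  expect_true(all(diff(cline_eval(p2, x)) < 0))
})

test_that("parameter invariants are enforced", {
  expect_error(logistic5(B = 0.5, T = 0.4, b = 0.001, xmid = 0, s = 1),
               "B < T")
  expect_error(logistic5(b = -0.001, xmid = 0, s = 1), "positive")
  expect_error(logistic5(b = 0.001, xmid = 0, s = 0), "positive")
})

test_that("closed-form inversion is exact and matches a bisection oracle", {
  p <- logistic5(b = 0.0012, xmid = 3400, s = 1)
  expect_equal(invert_cline(p, 0.5), 3400)   # symmetric case: the midpoint
  expect_error(invert_cline(p, 1.2), class = "clinedrift_domain_error")

  set.seed(101)
  for (i in 1:60) {
    pars <- random_logistic5()
    y <- runif(1, pars[["B"]] + 0.02, pars[["T"]] - 0.02)
    x <- invert_cline(pars, y)
    expect_equal(cline_eval(pars, x), y, tolerance = 1e-9)
    # independent bisection root-finder
    lo <- pars[["xmid"]] - 1e6; hi <- pars[["xmid"]] + 1e6
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (cline_eval(pars, mid) > y) lo <- mid else hi <- mid
    }
    expect_equal(x, (lo + hi) / 2, tolerance = 1e-6)
  }
})

test_that("invert is the inverse of eval across random positions", {
  set.seed(7)
  for (i in 1:20) {
    pars <- random_logistic5()
    x <- runif(100, pars[["xmid"]] - 2000, pars[["xmid"]] + 2000)
    y <- cline_eval(pars, x)
    ok <- y > pars[["B"]] + 1e-12 & y < pars[["T"]] - 1e-12
    expect_equal(invert_cline(pars, y[ok]), x[ok], tolerance = 1e-6)
  }
})

test_that("frequency points are ordered on any valid curve", {
  set.seed(33)
  for (i in 1:50) {
    pars <- random_logistic5()
    if (pars[["B"]] >= 0.2 || pars[["T"]] <= 0.8) next
    xs <- invert_cline(pars, c(0.8, 0.5, 0.2))
    expect_true(xs[1] <= xs[2] && xs[2] <= xs[3])
  }
})

test_that("fitting recovers known parameters from noiseless bins", {
  truth <- logistic5(B = 0.05, T = 0.95, b = 0.0015, xmid = 4000, s = 1.6)
  x <- seq(500, 9500, length.out = 15)
  fit <- fit_cline(x, cline_eval(truth, x), fix_asymptotes = "no")
  expect_true(fit$converged)
  expect_equal(unclass(fit$params), unclass(truth), tolerance = 1e-5)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$gof, 1, tolerance = 1e-8)
})

test_that("fitting is deterministic and invariant to row order", {
  set.seed(5)
  truth <- logistic5(b = 0.0012, xmid = 3000, s = 1)
  x <- seq(0, 8000, by = 400)
  y <- pmin(pmax(cline_eval(truth, x) + rnorm(length(x), 0, 0.05), 0), 1)
  f1 <- fit_cline(x, y)
  f2 <- fit_cline(x, y)
  expect_identical(unclass(f1$params), unclass(f2$params))
  o <- sample(length(x))
  f3 <- fit_cline(x[o], y[o])
  expect_identical(unclass(f1$params), unclass(f3$params))
})

test_that("degenerate inputs are refused with informative errors", {
  expect_error(fit_cline(1:10 * 100, rep(0.4, 10)),
               class = "clinedrift_degenerate_error")
  expect_error(fit_cline(c(100, 200), c(0.9, 0.1)), "at least")
  expect_error(fit_cline(1:6 * 100, c(0.9, 0.8, 0.7, 0.5, 0.3, 1.4)),
               "\\[0, 1\\]")
})

test_that("goodness of fit behaves like a pseudo-R-squared", {
  obs <- c(0.95, 0.9, 0.7, 0.4, 0.15, 0.05)
  expect_equal(unname(goodness_of_fit(obs, obs)["gof"]), 1)
  expect_error(goodness_of_fit(rep(0.5, 5), rep(0.4, 5)), "undefined")

  # fit to pure noise around a flat mean explains ~nothing
  set.seed(19)
  x <- seq(0, 8000, by = 250)
  y <- pmin(pmax(0.5 + rnorm(length(x), 0, 0.15), 0), 1)
  fit <- fit_cline(x, y, fix_asymptotes = "no")
  expect_lt(fit$gof, 0.35)

  # on least-squares fits, down-weighting large residuals helps the
  # weighted score: nearly-exact bins dominate the weighted decomposition
  for (i in 1:10) {
    truth <- logistic5(b = 10^runif(1, -3.5, -2.5),
                       xmid = runif(1, 2000, 6000), s = runif(1, 0.5, 2))
    xs <- seq(0, 10000, by = 400)
    ys <- pmin(pmax(cline_eval(truth, xs) + rnorm(length(xs), 0, 0.06), 0), 1)
    f <- fit_cline(xs, ys)
    expect_gte(f$weighted_gof + 1e-9, f$gof)
    expect_lte(f$weighted_gof, 1)
  }
})

test_that("predict, residuals and coef expose the fitted model", {
  truth <- logistic5(b = 0.0012, xmid = 3400, s = 1)
  x <- seq(200, 7800, by = 400)
  fit <- fit_cline(x, cline_eval(truth, x))
  expect_named(coef(fit), c("B", "T", "b", "xmid", "s"))
  expect_equal(predict(fit, newdata = 3400), 0.5, tolerance = 1e-6)
  expect_equal(length(residuals(fit)), fit$n_bins)
  expect_equal(fitted(fit) + residuals(fit), fit$data$freq)
  expect_output(print(fit), "logistic cline fit")
  expect_output(print(summary(fit)), "frequency points")
})
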