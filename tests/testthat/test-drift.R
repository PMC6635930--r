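test_that("interval rates are signed average velocities", {
  expect_equal(interval_rate(3420, 7026, 1991, 2016), 144.24)
  expect_equal(round(interval_rate(3420, 7026, 1991, 2016)), 144)
  expect_equal(interval_rate(3900, 9700, 1991, 2016), 232)
  expect_equal(interval_rate(500, 500, 1991, 2016), 0)
  # retreating metric keeps its negative sign
  expect_equal(interval_rate(4106, 3736, 1996, 2001), -74)
  expect_error(interval_rate(0, 1, 2000, 2000), "interval")
})

test_that("a union of adjacent intervals gives the duration-weighted mean rate", {
  set.seed(21)
  for (i in 1:20) {
    yrs <- sort(2000 + sample(1:30, 3))
    pos <- rnorm(3, 0, 1000)
    r1 <- interval_rate(pos[1], pos[2], yrs[1], yrs[2])
    r2 <- interval_rate(pos[2], pos[3], yrs[2], yrs[3])
    w <- diff(yrs)
    expect_equal(interval_rate(pos[1], pos[3], yrs[1], yrs[3]),
                 (r1 * w[1] + r2 * w[2]) / sum(w))
  }
})

test_that("trend fitting matches the closed-form OLS oracle", {
  tab <- published_metrics()
  for (m in c("nGc", "x08", "ip", "x02", "sGa")) {
    tr <- fit_trend(tab$year, tab[[m]], metric_name = m)
    o <- ols_oracle(tab$year, tab[[m]])
    expect_equal(tr$slope, o[["slope"]], tolerance = 1e-9)
    expect_equal(tr$intercept, o[["intercept"]], tolerance = 1e-9)
    # t from r reproduces the textbook identity
    r <- cor(tab$year, tab[[m]])
    expect_equal(tr$t_stat, r * sqrt(2 / (1 - r^2)), tolerance = 1e-9)
    expect_equal(tr$p, pt(tr$t_stat, 2, lower.tail = FALSE), tolerance = 1e-12)
  }
  # spot value computed by hand from the published positions
  expect_equal(fit_trend(tab$year, tab$ip)$slope, 142.957, tolerance = 1e-3)

  set.seed(9)
  for (i in 1:25) {
    yrs <- sort(1990 + sample(0:40, 5))
    pos <- 100 * yrs + rnorm(5, 0, 500) - 2e5
    tr <- fit_trend(yrs, pos)
    o <- ols_oracle(yrs, pos)
    expect_equal(unname(coef(tr)), unname(o), tolerance = 1e-9)
  }
})

test_that("trend edge cases: collinear points, reversal, two points", {
  tr <- fit_trend(c(1990, 2000, 2010), c(0, 1000, 2000))
  expect_equal(tr$r, 1, tolerance = 1e-7)
  expect_gt(tr$p, 0)                       # machine floor, never exactly 0
  expect_lt(tr$p, 1e-6)

  yrs <- c(1991, 1996, 2001, 2016)
  pos <- c(3420, 4231, 4547, 7026)
  expect_equal(fit_trend(yrs, -pos)$slope, -fit_trend(yrs, pos)$slope)

  two <- fit_trend(c(1991, 2016), c(3900, 9700))
  expect_equal(two$slope, 232)
  expect_true(is.na(two$p))
  expect_error(fit_trend(c(2000, 2000), c(1, 2)), "distinct")
})

test_that("x-intercept year dates the arrival at the transect origin", {
  # line through (2016, 9700) with slope 232
  tr <- fit_trend(c(1991, 2016), c(9700 - 232 * 25, 9700))
  expect_equal(x_intercept_year(tr), 2016 - 9700 / 232, tolerance = 1e-9)
  expect_equal(round(2016 - x_intercept_year(tr)), 42)

  # planted crossing year recovered exactly
  yrs <- c(1995, 2000, 2005, 2010)
  tr2 <- fit_trend(yrs, 120 * (yrs - 1972.25))
  expect_equal(x_intercept_year(tr2), 1972.25, tolerance = 1e-9)

  # shifting all years shifts the estimate equally
  tab <- published_metrics()
  t0 <- x_intercept_year(fit_trend(tab$year, tab$ip))
  t1 <- x_intercept_year(fit_trend(tab$year + 7, tab$ip))
  expect_equal(t1, t0 + 7, tolerance = 1e-9)

  retreating <- fit_trend(c(1990, 2000, 2010), c(520, 500, 470))
  expect_error(x_intercept_year(retreating), "southward")
})

test_that("arrival aggregation is the mean and sample SD of crossing years", {
  tr <- fit_trend(c(1991, 2016), c(9700 - 232 * 25, 9700))
  same <- replicate(5, tr, simplify = FALSE)
  agg <- aggregate_arrival(same)
  expect_equal(agg[["sd_years"]], 0)
  expect_equal(agg[["mean_year"]], x_intercept_year(tr))

  two <- list(fit_trend(c(1990, 2000), c(0, 1000)),
              fit_trend(c(1990, 2000), c(500, 1500)))
  yrs <- sapply(two, x_intercept_year)
  agg2 <- aggregate_arrival(two)
  expect_equal(agg2[["mean_year"]], mean(yrs))
  expect_equal(agg2[["sd_years"]], sqrt(sum((yrs - mean(yrs))^2) / 1))
  expect_error(aggregate_arrival(two[1]), "at least two")
})

test_that("travel time is distance over rate", {
  expect_equal(travel_time(9700, 232), 41.81, tolerance = 0.005)
  expect_equal(round(travel_time(8970, 232)), 39)
  expect_equal(travel_time(0, 150), 0)
  expect_error(travel_time(100, -1), "positive")
  expect_error(travel_time(-5, 100), "non-negative")
})

test_that("dispersal estimates split diffusion from jump dispersal", {
  tab <- published_metrics()
  d <- dispersal_estimates(tab)
  expect_equal(d$mean_annual, 149.3, tolerance = 0.05)
  expect_equal(d$sd_annual, 5.64, tolerance = 0.01)
  expect_equal(d$max_annual, 242.86, tolerance = 0.01)
  expect_gt(d$max_annual, d$mean_annual)
})

test_that("full width grows when the leading edge outruns the trailing edge", {
  tab <- published_metrics()
  tr <- metric_trends(tab)
  expect_gt(tr$sGa$slope, tr$nGc$slope)
  fitted_widths <- predict(tr$sGa) - predict(tr$nGc)
  expect_true(all(diff(fitted_widths) > 0))
})

test_that("the drift table reports consecutive and full-span rates", {
  tab <- published_metrics()
  d <- drift_table(tab, digits = 0)
  expect_equal(d$interval,
               c("1991-1996", "1996-2001", "2001-2016", "1991-2016"))
  expect_equal(d$years, c(5, 5, 15, 25))
  full <- d[d$interval == "1991-2016", ]
  expect_equal(unlist(full[c("nGc", "x08", "ip", "x02", "sGa")],
                      use.names = FALSE),
               c(104, 163, 144, 150, 232))
})
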