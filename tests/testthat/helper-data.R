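# shared fixtures, built in code

# per-survey zone positions as published for the study transect
# (meters south of the origin landmark)
published_metrics <- function() {
  zone_metrics_table(
    zone_metrics_row(1991, nGc = 2300, x08 = 2492, ip = 3420,
                     x02 = 3760, sGa = 3900),
    zone_metrics_row(1996, nGc = 3800, x08 = 4106, ip = 4231,
                     x02 = 4266, sGa = 4300),
    zone_metrics_row(2001, nGc = 3600, x08 = 3736, ip = 4547,
                     x02 = 4786, sGa = 6400),
    zone_metrics_row(2016, nGc = 4900, x08 = 6558, ip = 7026,
                     x02 = 7516, sGa = 9700)
  )
}

make_records <- function(position_m, n_north, n_south, year = 2016) {
  df <- data.frame(
    host_id = sprintf("h%02d", seq_along(position_m)),
    year = year, position_m = position_m,
    n_north = n_north, n_south = n_south,
    stringsAsFactors = FALSE
  )
  suppressMessages(as_specimen_records(df))
}

# hand two-variable OLS, independent of lm()
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

random_logistic5 <- function() {
  B <- runif(1, 0, 0.3)
  logistic5(B = B, T = runif(1, 0.7, 1), b = 10^runif(1, -4, -2),
            xmid = runif(1, 0, 10000), s = runif(1, 0.2, 5))
}
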