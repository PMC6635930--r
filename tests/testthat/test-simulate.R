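test_that("the generating cline translates at the configured velocity", {
  cfg <- zone_sim_config(v = 150, c0 = 3400, t0 = 1991, seed = 1)
  c1 <- true_cline(cfg, 1991)
  c2 <- true_cline(cfg, 2001)
  expect_equal(invert_cline(c1, 0.5), 3400, tolerance = 1e-9)
  expect_equal(invert_cline(c2, 0.5) - invert_cline(c1, 0.5), 1500,
               tolerance = 1e-9)
  expect_error(true_cline(cfg, 1980), "precede")
})

test_that("the generating slope reproduces the requested 0.2-0.8 width", {
  for (s in c(0.4, 1, 2.7)) {
    cfg <- zone_sim_config(width_0208 = 1000, s = s, seed = 1)
    tc <- true_cline(cfg, 1991)
    expect_equal(invert_cline(tc, 0.2) - invert_cline(tc, 0.8), 1000,
                 tolerance = 1e-9)
    # the 50% crossing sits at the configured center for every asymmetry
    expect_equal(invert_cline(tc, 0.5), 3400, tolerance = 1e-9)
  }
  # s = 1 closed form: b = 2 log10(4) / width
  tc <- true_cline(zone_sim_config(width_0208 = 1000, s = 1, seed = 1), 1991)
  expect_equal(tc[["b"]], 2 * log10(4) / 1000, tolerance = 1e-12)
})

test_that("config invariants are enforced", {
  expect_error(zone_sim_config(v = -5), "positive")
  expect_error(zone_sim_config(mixed_deficit = 1.5), "\\[0, 1\\]")
  expect_error(zone_sim_config(transect_span = c(5000, 1000)), "increasing")
  expect_error(zone_sim_config(survey_years = c(1700, 1991)), "window")
})

test_that("surveys are reproducible from the seed and leave the RNG alone", {
  cfg <- zone_sim_config(seed = 42)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  r1 <- simulate_survey(cfg, 2001)
  after <- runif(1)
  r2 <- simulate_survey(cfg, 2001)
  expect_identical(r1, r2)
  expect_identical(before, after)   # caller RNG stream untouched
  # different years and seeds give different draws
  r3 <- simulate_survey(cfg, 2016)
  expect_false(identical(r1$position_m, r3$position_m))
  r4 <- simulate_survey(zone_sim_config(seed = 43), 2001)
  expect_false(identical(r1$position_m, r4$position_m))
})

test_that("simulated records are valid and class ratios follow the construction", {
  cfg <- zone_sim_config(seed = 5, jump_rate = 0, lag_rate = 0)
  rec <- simulate_survey(cfg, 1996)
  expect_s3_class(rec, "specimen_records")
  expect_true(all(rec$n_north + rec$n_south >= 1))
  expect_true(all(rec$position_m >= 0 & rec$position_m <= 12000))
  expect_true(all(rec$year == 1996))

  # at a p = 0.5 locale with no deficit, classes approach 1:2:1
  cfg2 <- zone_sim_config(mixed_deficit = 1, host_density = 4000,
                          transect_span = c(4100, 4200), width_0208 = 20000,
                          c0 = 4150, t0 = 1991, survey_years = 1991,
                          jump_rate = 0, lag_rate = 0, seed = 8)
  rec2 <- simulate_survey(cfg2, 1991)
  frac <- as.numeric(table(rec2$sample_class)) / nrow(rec2)
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.08)

  # mixed hosts carry both species with the minority below one half
  mixed <- rec2[rec2$sample_class == "MIXED", ]
  expect_true(all(mixed$n_north >= 1 & mixed$n_south >= 1))
  expect_true(mean(pmin(mixed$n_north, mixed$n_south) /
                     (mixed$n_north + mixed$n_south)) < 0.5)
})

test_that("binned frequencies converge to the generating cline with density", {
  cfg <- zone_sim_config(host_density = 150, jump_rate = 0, lag_rate = 0,
                         mixed_deficit = 1, seed = 314)
  rec <- simulate_survey(cfg, 1991)
  b <- bin_frequencies(rec)
  truth <- cline_eval(true_cline(cfg, 1991), b$x_center_m)
  expect_lt(mean(abs(b$freq_north - truth)), 0.05)
})

test_that("planted jump and lag hosts shape the raw extremes", {
  cfg <- zone_sim_config(jump_rate = 8, lag_rate = 8, seed = 99)
  rec <- simulate_survey(cfg, 2001)
  tc <- true_cline(cfg, 2001)
  ext <- extreme_positions(rec)
  expect_gte(ext[["sGa"]], invert_cline(tc, 0.2))
  expect_lte(ext[["nGc"]], invert_cline(tc, 0.8))
})

test_that("a mixed-sample deficit is detectable and grows with sample size", {
  p_for_n <- function(density, seed) {
    cfg <- zone_sim_config(mixed_deficit = 0.4, host_density = density,
                           transect_span = c(2400, 4400), survey_years = 1991,
                           jump_rate = 0, lag_rate = 0, seed = seed)
    rec <- simulate_survey(cfg, 1991)
    tc <- true_cline(cfg, 1991)
    m <- zone_metrics_row(1991, x08 = invert_cline(tc, 0.8),
                          ip = invert_cline(tc, 0.5),
                          x02 = invert_cline(tc, 0.2))
    inz <- suppressMessages(in_zone_records(rec, m))
    mixed_proportion_test(as.integer(table(inz$sample_class)))$p.value
  }
  small <- sapply(1:20, function(s) p_for_n(30, s))
  large <- sapply(1:20, function(s) p_for_n(400, s))
  expect_gt(mean(small < 0.05), 0.2)      # some power already at ~30 hosts
  expect_gt(mean(large < 0.05), 0.9)      # near-certain rejection when large
  expect_gt(mean(large < 0.05), mean(small < 0.05))
})

test_that("fixtures round-trip through disk with a faithful manifest", {
  dir <- withr::local_tempdir()
  cfg <- zone_sim_config(seed = 77, survey_years = c(1991, 2016))
  manifest <- write_fixture(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (y in c("1991", "2016")) {
    f <- file.path(dir, paste0("survey_", y, ".csv"))
    expect_true(file.exists(f))
    back <- suppressMessages(read_survey(f))
    expect_equal(nrow(back), manifest$surveys[[y]]$n_records)
    direct <- simulate_survey(cfg, as.numeric(y))
    expect_equal(back$position_m, direct$position_m, tolerance = 1e-9)
    expect_equal(back$n_north, direct$n_north)
  }
  expect_equal(manifest$true_metrics[["1991"]]$ip, 3400, tolerance = 1e-9)
})
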