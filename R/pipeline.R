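#' Run the full replacement-zone analysis pipeline
#'
#' Orchestrates the stages of the analysis — optionally simulating a
#' synthetic zone, then binning each survey's records, fitting the
#' five-parameter logistic cline, extracting per-survey zone metrics,
#' regressing metrics on year (interval rates, trend tests, arrival
#' dating) and testing mixed-sample proportions — and writes a
#' reproducible report bundle of CSV/JSON files.
#'
#' The drift stage alternatively accepts an externally supplied metrics
#' table (`metrics_csv`), so published per-survey positions can be pushed
#' through rate and dating inference without raw records.
#'
#' @param config a named list, or a path to a YAML/JSON configuration
#'   file, with any of: `inputs` (named list or vector of survey CSV
#'   paths, names = decimal years), `simulate` (list of
#'   [zone_sim_config()] arguments, used when no `inputs` are given),
#'   `metrics_csv` (path to a ready-made metrics table; skips binning and
#'   fitting), `bin_width_m` (default 200), `origin_m` (default 0),
#'   `campaign_years` (named list remapping input years, e.g. a multi-year
#'   campaign to its representative year), `weights` (`"none"` or
#'   `"n_hosts"`), `fix_asymptotes`, `two_tailed` (default `FALSE`),
#'   `seed`, `out_dir`.
#' @param out_dir output directory, overriding the config.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `metrics`, `drift`, `trends`,
#'   `arrival`, `dispersal`, `mixed_test` and the paths written.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(simulate = list(seed = 1),
#'                          out_dir = tempfile("zone_run")))
#' out$metrics
#' }
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% file.path(tempdir(), "zone_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", ..., "]")
  bin_width <- config$bin_width_m %||% 200
  origin <- config$origin_m %||% 0
  weights <- config$weights %||% "none"
  fix_asym <- config$fix_asymptotes %||% "auto"
  two_tailed <- isTRUE(config$two_tailed)

  stage <- "input"
  result <- tryCatch({
    surveys <- NULL
    if (!is.null(config$metrics_csv)) {
      stage <- "metrics-input"
      say(stage, ": reading ", config$metrics_csv)
      m <- utils::read.csv(config$metrics_csv, check.names = FALSE)
      metrics <- zone_metrics_table(lapply(seq_len(nrow(m)), function(i) {
        zone_metrics_row(m$year[i], nGc = m$nGc[i] %||% NA_real_,
                         x08 = m$x08[i], ip = m$ip[i], x02 = m$x02[i],
                         sGa = m$sGa[i] %||% NA_real_)
      }))
    } else {
      if (!is.null(config$inputs)) {
        stage <- "load"
        inputs <- config$inputs
        surveys <- lapply(seq_along(inputs), function(i) {
          say("load: ", inputs[[i]])
          rec <- read_survey(inputs[[i]])
          yr <- suppressWarnings(as.numeric(names(inputs)[i]))
          if (length(yr) && !is.na(yr)) rec$year <- yr
          rec
        })
        names(surveys) <- vapply(surveys, function(r) as.character(r$year[1]),
                                 character(1))
      } else {
        stage <- "simulate"
        sim_args <- config$simulate %||% list()
        if (!is.null(config$seed)) sim_args$seed <- config$seed
        cfg <- do.call(zone_sim_config, sim_args)
        say("simulate: seed ", cfg$seed, ", surveys ",
            paste(cfg$survey_years, collapse = ", "))
        surveys <- simulate_zone(cfg)
        write_fixture(cfg, file.path(out_dir, "synthetic"))
      }
      campaign <- config$campaign_years %||% list()

      stage <- "fit"
      rows <- list()
      fit_reports <- list()
      for (y in names(surveys)) {
        rec <- surveys[[y]]
        year <- campaign[[y]] %||% as.numeric(y)
        bins <- bin_frequencies(rec, bin_width_m = bin_width,
                                origin_m = origin)
        utils::write.csv(bins, file.path(out_dir, paste0("bins_", y, ".csv")),
                         row.names = FALSE)
        fit <- fit_cline(bins,
                         weights = if (identical(weights, "n_hosts"))
                           "n_hosts" else NULL,
                         fix_asymptotes = fix_asym)
        say("fit ", y, ": GOF ", round(fit$gof, 4), ", converged ",
            fit$converged)
        fit_reports[[y]] <- cline_fit_report(fit)
        rows[[y]] <- suppressWarnings(zone_metrics(fit, rec, year = year))
      }
      write_json_report(fit_reports, file.path(out_dir, "cline_fits.json"))
      metrics <- zone_metrics_table(rows)
    }
    utils::write.csv(as.data.frame(metrics),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)

    stage <- "drift"
    metric_cols <- c("nGc", "x08", "ip", "x02", "sGa")
    usable <- metric_cols[colSums(!is.na(as.data.frame(metrics)[metric_cols])) >= 2]
    drift <- drift_table(metrics, metrics_names = usable)
    utils::write.csv(drift, file.path(out_dir, "drift.csv"),
                     row.names = FALSE)
    trends <- metric_trends(metrics, metrics_names = usable,
                            two_tailed = two_tailed)
    dated <- Filter(function(t) !is.na(t$slope) && t$slope > 0, trends)
    arrival <- if (length(dated) >= 2) aggregate_arrival(dated) else NULL
    dispersal <- if (all(c("x08", "ip", "x02", "sGa") %in% usable))
      dispersal_estimates(metrics) else NULL
    write_json_report(
      list(trends = lapply(trends, trend_report),
           arrival = as.list(arrival),
           dispersal = if (!is.null(dispersal))
             dispersal[c("mean_annual", "sd_annual", "max_annual")]),
      file.path(out_dir, "drift.json"))

    stage <- "mixedtest"
    mixed <- NULL
    if (!is.null(surveys)) {
      all_rec <- do.call(rbind, lapply(surveys, as.data.frame))
      class(all_rec) <- c("specimen_records", "data.frame")
      inz <- suppressMessages(in_zone_records(all_rec, metrics))
      counts <- as.integer(table(inz$sample_class))
      if (sum(counts) >= 1) {
        mixed <- mixed_proportion_test(counts)
        write_json_report(
          list(observed = as.list(mixed$observed),
               expected = as.list(mixed$expected),
               chi2 = unname(mixed$statistic), df = 2,
               p = mixed$p.value,
               zone_selection = attr(inz, "zone_selection")),
          file.path(out_dir, "mixed_test.json"))
      }
    }

    stage <- "log"
    write_json_report(
      list(package = "clinedrift",
           version = as.character(utils::packageVersion("clinedrift")),
           r_version = R.version.string,
           seed = config$seed %||% config$simulate$seed %||% NA,
           config = config,
           written = list.files(out_dir, recursive = TRUE)),
      file.path(out_dir, "run_log.json"))

    list(metrics = metrics, drift = drift, trends = trends,
         arrival = arrival, dispersal = dispersal, mixed_test = mixed,
         out_dir = out_dir)
  }, error = function(e) {
    stop_cd("pipeline failed at stage '", stage, "': ", conditionMessage(e),
            class = "clinedrift_pipeline_error")
  })
  invisible(result)
}

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yml`/`.yaml`, requires the yaml package) or JSON
#'   configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_cd("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_cd("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

cline_fit_report <- function(fit) {
  list(params = as.list(unclass(fit$params)),
       n_bins = fit$n_bins,
       sse = fit$sse,
       gof = fit$gof,
       weighted_gof = fit$weighted_gof,
       converged = fit$converged,
       fixed_asymptotes = fit$fixed_asymptotes,
       residuals = fit$residuals,
       optim = fit$optim)
}

trend_report <- function(t) {
  list(metric = t$metric_name, slope = t$slope, intercept = t$intercept,
       r = t$r, t_stat = t$t_stat, df = t$df, p = t$p,
       two_tailed = t$two_tailed, n = t$n,
       x_intercept_year = t$x_intercept_year)
}
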