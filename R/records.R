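#' Read host/parasite survey records
#'
#' Reads a CSV or TSV of survey records, one row per host, validates it and
#' returns a normalised `data.frame` of specimen records. The logical
#' columns are `host_id`, `year` (decimal calendar year), `position_m`
#' (signed meters along a north--south transect, positive = south of the
#' origin landmark), and per-species louse counts `n_north` and `n_south`.
#' Physical column names can differ; supply `column_map` to remap them.
#' Datasets without per-louse counts may instead carry a `sample_class`
#' column with values `PURE_NORTH` / `MIXED` / `PURE_SOUTH`; counts take
#' precedence when both are present.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping logical names to the
#'   file's column names, e.g. `c(position_m = "dist_south")`. Unmapped
#'   logical names are looked up verbatim.
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.tab` means tab, otherwise comma).
#' @param year_window plausible calendar-year window; rows outside it are
#'   rejected.
#' @return A `data.frame` of class `"specimen_records"` with columns
#'   `host_id`, `year`, `position_m`, `n_north`, `n_south` and
#'   `sample_class` (factor).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(host_id = c("a", "b", "c"), year = 2016,
#'                      position_m = c(5100, 5300, 5450),
#'                      n_north = c(40, 12, 0), n_south = c(0, 3, 18)),
#'           f, row.names = FALSE)
#' rec <- read_survey(f)
#' table(rec$sample_class)
#' @seealso [classify_sample()], [bin_frequencies()], [write_survey()]
#' @export
read_survey <- function(path, column_map = NULL, sep = NULL,
                        year_window = c(1850, 2100)) {
  if (!file.exists(path)) stop_cd("survey file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"",
                           fileEncoding = "UTF-8")
  as_specimen_records(raw, column_map = column_map, year_window = year_window,
                      source = path)
}

#' Validate a data frame of specimen records
#'
#' Lower-level companion to [read_survey()] for records already in memory.
#'
#' @inheritParams read_survey
#' @param df a data.frame with the survey columns.
#' @param source label used in error messages.
#' @return A validated `"specimen_records"` data.frame.
#' @export
as_specimen_records <- function(df, column_map = NULL,
                                year_window = c(1850, 2100),
                                source = "records") {
  logical_cols <- c("host_id", "year", "position_m", "n_north", "n_south",
                    "sample_class")
  map <- stats::setNames(logical_cols, logical_cols)
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  have_counts <- all(map[c("n_north", "n_south")] %in% names(df))
  have_class <- map[["sample_class"]] %in% names(df)
  required <- c("host_id", "year", "position_m",
                if (!have_class) c("n_north", "n_south"))
  missing <- required[!map[required] %in% names(df)]
  if (length(missing)) {
    stop_cd("missing required column(s) in ", source, ": ",
            paste(map[missing], collapse = ", "),
            class = "clinedrift_schema_error")
  }

  known <- unname(map[c(required, if (have_counts) c("n_north", "n_south"),
                        if (have_class) "sample_class")])
  extras <- setdiff(names(df), known)
  if (length(extras)) {
    warning("ignoring unrecognised column(s) in ", source, ": ",
            paste(extras, collapse = ", "), call. = FALSE)
  }

  out <- data.frame(host_id = as.character(df[[map[["host_id"]]]]),
                    stringsAsFactors = FALSE)
  for (col in c("year", "position_m")) {
    v <- df[[map[[col]]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) | !is.finite(vn))
    if (length(bad)) {
      stop_cd("non-numeric or missing ", col, " in ", source,
              " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    out[[col]] <- vn
  }
  outside <- which(out$year < year_window[1] | out$year > year_window[2])
  if (length(outside)) {
    stop_cd("year outside plausible window [", year_window[1], ", ",
            year_window[2], "] at row(s) ",
            paste(utils::head(outside, 5), collapse = ", "))
  }

  if (have_counts) {
    for (col in c("n_north", "n_south")) {
      v <- suppressWarnings(as.numeric(df[[map[[col]]]]))
      bad <- which(is.na(v) | v < 0 | v != round(v))
      if (length(bad)) {
        stop_cd(col, " must be a non-negative integer count; bad row(s) ",
                paste(utils::head(bad, 5), collapse = ", "), " in ", source)
      }
      out[[col]] <- as.integer(v)
    }
    empty <- which(out$n_north + out$n_south == 0)
    if (length(empty)) {
      stop_cd("record with zero lice of either species at row(s) ",
              paste(utils::head(empty, 5), collapse = ", "), " in ", source)
    }
    out$sample_class <- classify_sample(out$n_north, out$n_south)
    if (have_class) {
      given <- factor(as.character(df[[map[["sample_class"]]]]),
                      levels = levels(out$sample_class))
      if (any(!is.na(given) & given != out$sample_class)) {
        warning("sample_class column disagrees with counts; counts take ",
                "precedence", call. = FALSE)
      }
    }
  } else {
    cls <- factor(as.character(df[[map[["sample_class"]]]]),
                  levels = c("PURE_NORTH", "MIXED", "PURE_SOUTH"))
    if (anyNA(cls)) {
      stop_cd("sample_class must be PURE_NORTH, MIXED or PURE_SOUTH; bad ",
              "row(s) ", paste(utils::head(which(is.na(cls)), 5),
                               collapse = ", "), " in ", source)
    }
    # minimal counts consistent with the class, for code paths that need them
    out$n_north <- ifelse(cls == "PURE_SOUTH", 0L, 1L)
    out$n_south <- ifelse(cls == "PURE_NORTH", 0L, 1L)
    out$sample_class <- cls
  }
  message(nrow(out), " specimen record(s) loaded from ", source)
  class(out) <- c("specimen_records", "data.frame")
  out
}

#' Classify a host's louse sample
#'
#' A host's sample is `PURE_NORTH` when it contains only the northern
#' species, `PURE_SOUTH` when only the southern species, and `MIXED` when
#' both species are present, regardless of their proportions.
#'
#' @param n_north,n_south non-negative louse counts (vectorised); each
#'   sample must contain at least one louse.
#' @return Factor with levels `PURE_NORTH`, `MIXED`, `PURE_SOUTH`.
#' @examples
#' classify_sample(c(40, 1, 0), c(0, 39, 5))
#' @export
classify_sample <- function(n_north, n_south) {
  if (length(n_north) != length(n_south)) {
    stop_cd("count vectors must have equal length")
  }
  if (any(n_north < 0 | n_south < 0)) stop_cd("counts must be non-negative")
  if (any(n_north + n_south < 1)) {
    stop_cd("empty sample: each record needs at least one louse")
  }
  factor(ifelse(n_south == 0, "PURE_NORTH",
                ifelse(n_north == 0, "PURE_SOUTH", "MIXED")),
         levels = c("PURE_NORTH", "MIXED", "PURE_SOUTH"))
}

#' Bin invader frequency along the transect
#'
#' Groups records into fixed-width bins along the transect (half-open
#' intervals `[k w, (k+1) w)` measured from `origin_m`) and computes the
#' frequency of hosts carrying the northern (invading) species per bin,
#' with the half-count rule: a mixed-species host counts as half a northern
#' and half a southern host. A bin of five hosts, four pure-north and one
#' mixed, therefore scores 4.5/5 = 90%.
#'
#' @param records a `"specimen_records"` data.frame (or anything
#'   [as_specimen_records()] accepts).
#' @param bin_width_m bin width in meters (default 200).
#' @param origin_m bin anchor in meters (default 0, the origin landmark).
#' @return A `data.frame` with one row per non-empty bin: `bin_index`,
#'   `x_center_m` (bin midpoint), `n_hosts`, `freq_north`.
#' @examples
#' rec <- data.frame(host_id = letters[1:5], year = 2016,
#'                   position_m = c(5010, 5050, 5090, 5130, 5170),
#'                   n_north = c(30, 25, 41, 18, 9),
#'                   n_south = c(0, 0, 0, 0, 22))
#' bin_frequencies(rec)   # one bin, freq_north = 0.9
#' @export
bin_frequencies <- function(records, bin_width_m = 200, origin_m = 0) {
  if (!inherits(records, "specimen_records")) {
    records <- suppressMessages(as_specimen_records(records))
  }
  if (nrow(records) == 0) stop_cd("no records to bin")
  if (bin_width_m <= 0) stop_cd("bin_width_m must be positive")

  idx <- floor((records$position_m - origin_m) / bin_width_m)
  cls <- records$sample_class
  half_counts <- (cls == "PURE_NORTH") + 0.5 * (cls == "MIXED")
  agg_n <- tapply(half_counts, idx, length)
  agg_f <- tapply(half_counts, idx, sum)
  bins <- sort(unique(idx))
  out <- data.frame(
    bin_index = as.integer(bins),
    x_center_m = origin_m + (bins + 0.5) * bin_width_m,
    n_hosts = as.integer(agg_n[as.character(bins)]),
    freq_north = as.numeric(agg_f[as.character(bins)] /
                              agg_n[as.character(bins)])
  )
  rownames(out) <- NULL
  out
}

#' Write specimen records to CSV
#'
#' @param records a `"specimen_records"` data.frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_survey <- function(records, path) {
  cols <- c("host_id", "year", "position_m", "n_north", "n_south")
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
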