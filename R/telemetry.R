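#' Detection filter settings
#'
#' Collects the three exclusion rules applied to raw automated-telemetry
#' detections before any roost assignment: a run-length floor (short runs are
#' false positives), an overnight time window (roosting, not foraging,
#' detections), and a season cutoff (excluding migration-period movement).
#'
#' @param max_false_positive_run runs of this length or shorter are treated
#'   as false positives and removed (default 3).
#' @param window_start,window_end time of day, `"HH:MM"` or seconds since
#'   midnight. The kept window runs from `window_start` (inclusive) to
#'   `window_end` (exclusive) and may span midnight; the default 18:00–10:00
#'   keeps evening-through-morning roosting detections.
#' @param season_cutoff `Date` (or string) — detections at or after local
#'   midnight of this date are excluded. Default 1 September 2019.
#' @param tz Olson time zone in which timestamps are interpreted
#'   (default `"America/Halifax"`, Atlantic local time).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_false_positive_run = 3L,
                          window_start = "18:00",
                          window_end = "10:00",
                          season_cutoff = "2019-09-01",
                          tz = "America/Halifax") {
  max_false_positive_run <- as.integer(max_false_positive_run)
  if (is.na(max_false_positive_run) || max_false_positive_run < 0L) {
    stop_config("max_false_positive_run must be a nonnegative integer")
  }
  ws <- parse_tod(window_start)
  we <- parse_tod(window_end)
  if (ws == we) stop_config("window_start and window_end must differ")
  structure(
    list(
      max_false_positive_run = max_false_positive_run,
      window_start = ws,
      window_end = we,
      season_cutoff = as.Date(season_cutoff),
      tz = tz
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  fmt <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  cat("Detection filter config\n",
      "  run length    : keep > ", x$max_false_positive_run, "\n",
      "  time window   : [", fmt(x$window_start), ", ", fmt(x$window_end), ")\n",
      "  season cutoff : before ", format(x$season_cutoff), " 00:00 ", x$tz, "\n",
      sep = "")
  invisible(x)
}

# Row-wise timestamp parsing: each row may use any accepted format, and a
# failure poisons only its own row.
parse_timestamps <- function(x, tz) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = tz))
  }
  out
}

default_column_map <- function() {
  c(tag_id = "motusTagID", timestamp = "ts",
    tower_id = "recvDeployName", run_length = "runLen")
}

new_detections <- function(tag_id, timestamp, tower_id, run_length) {
  data.frame(
    tag_id = as.character(tag_id),
    timestamp = timestamp,
    tower_id = as.character(tower_id),
    run_length = as.integer(run_length),
    stringsAsFactors = FALSE
  )
}

#' Read an automated-telemetry detection table
#'
#' Reads a delimited detection export (one row per detection) and returns a
#' validated detection table with columns `tag_id`, `timestamp` (POSIXct in
#' the configured zone), `tower_id` and `run_length`.
#'
#' @param source path to a delimited text file, or a connection.
#' @param column_map named character vector mapping the internal names
#'   `tag_id`, `timestamp`, `tower_id`, `run_length` to the file's column
#'   names. The default matches common Motus exports
#'   (`motusTagID`, `ts`, `recvDeployName`, `runLen`).
#' @param tz time zone for timestamp parsing (default `"America/Halifax"`).
#' @param delim field delimiter (default `","`).
#' @param strict if `TRUE` (default) any malformed row (unparseable
#'   timestamp, non-positive run length) aborts with the offending row
#'   numbers; if `FALSE` such rows are dropped with a warning.
#' @return A `data.frame` of detections.
#' @export
read_detections <- function(source,
                            column_map = default_column_map(),
                            tz = "America/Halifax",
                            delim = ",",
                            strict = TRUE) {
  full_map <- default_column_map()
  full_map[names(column_map)] <- column_map
  raw <- utils::read.table(source, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  missing <- setdiff(unname(full_map), names(raw))
  if (length(missing) > 0) {
    stop_config("mapped column(s) absent from input: ",
                paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(new_detections(character(), as.POSIXct(character(), tz = tz),
                          character(), integer()))
  }
  ts <- parse_timestamps(raw[[full_map[["timestamp"]]]], tz)
  rl <- suppressWarnings(as.integer(raw[[full_map[["run_length"]]]]))
  bad <- which(is.na(ts) | is.na(rl) | rl < 1L)
  if (length(bad) > 0) {
    msg <- paste0("malformed detection row(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop_data(msg)
    warning(msg, " (dropped)", call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  new_detections(raw[[full_map[["tag_id"]]]][keep], ts[keep],
                 raw[[full_map[["tower_id"]]]][keep], rl[keep])
}

#' Write detections back to CSV
#'
#' Inverse of [read_detections()]: serialises a detection table using the
#' same column mapping, so filtered data round-trip losslessly.
#'
#' @param detections detection `data.frame`.
#' @param path output file path.
#' @param column_map as in [read_detections()].
#' @export
write_detections <- function(detections, path,
                             column_map = default_column_map()) {
  full_map <- default_column_map()
  full_map[names(column_map)] <- column_map
  out <- data.frame(
    a = detections$tag_id,
    b = format(detections$timestamp, "%Y-%m-%d %H:%M:%S"),
    c = detections$tower_id,
    d = detections$run_length,
    stringsAsFactors = FALSE
  )
  names(out) <- unname(full_map[c("tag_id", "timestamp", "tower_id", "run_length")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove short (false-positive) detection runs
#'
#' Detections belonging to runs of `max_false_positive_run` or fewer
#' consecutive detections are treated as false positives and removed; the
#' run length is taken as reported per record, not recomputed.
#'
#' @param detections detection `data.frame`.
#' @param config a [filter_config()].
#' @return The detections with `run_length > max_false_positive_run`,
#'   in input order.
#' @export
filter_run_length <- function(detections, config = filter_config()) {
  detections[detections$run_length > config$max_false_positive_run, ,
             drop = FALSE]
}

#' Keep detections inside the overnight roosting window
#'
#' Keeps detections whose local time of day falls in the half-open window
#' `[window_start, window_end)`. When the window spans midnight (the default
#' 18:00–10:00) a detection is kept when its time of day is at or after
#' `window_start` or strictly before `window_end`.
#'
#' @inheritParams filter_run_length
#' @return The detections inside the window, in input order.
#' @export
filter_time_window <- function(detections, config = filter_config()) {
  tod <- seconds_of_day(detections$timestamp)
  ws <- config$window_start
  we <- config$window_end
  keep <- if (ws > we) tod >= ws | tod < we else tod >= ws & tod < we
  detections[keep, , drop = FALSE]
}

#' Remove detections after the season cutoff
#'
#' Keeps detections strictly before local midnight of the cutoff date
#' (default 1 September), excluding late-season records likely to represent
#' migration rather than breeding-season roost use.
#'
#' @inheritParams filter_run_length
#' @return The detections before the cutoff, in input order.
#' @export
filter_season <- function(detections, config = filter_config()) {
  cutoff <- as.POSIXct(paste(format(config$season_cutoff), "00:00:00"),
                       tz = config$tz)
  detections[detections$timestamp < cutoff, , drop = FALSE]
}

#' Apply all detection filters
#'
#' Convenience composition of [filter_run_length()], [filter_time_window()]
#' and [filter_season()]; the three are order-independent.
#'
#' @inheritParams filter_run_length
#' @param verbose if `TRUE`, report counts dropped by each rule.
#' @return The filtered detection table.
#' @export
filter_detections <- function(detections, config = filter_config(),
                              verbose = FALSE) {
  n0 <- nrow(detections)
  d1 <- filter_run_length(detections, config)
  d2 <- filter_time_window(d1, config)
  d3 <- filter_season(d2, config)
  if (verbose) {
    message(sprintf(
      "detections: %d in; %d short-run, %d out-of-window, %d post-season dropped; %d kept",
      n0, n0 - nrow(d1), nrow(d1) - nrow(d2), nrow(d2) - nrow(d3), nrow(d3)))
  }
  d3
}
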