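#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km,
#' vectorised over pairs of WGS84 decimal-degree coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(44, -65, 45, -65) # one degree of latitude, ~111.19 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) {
    all(lat >= -90 & lat <= 90, na.rm = TRUE) &&
      all(lon >= -180 & lon <= 180, na.rm = TRUE) &&
      !anyNA(c(lat, lon))
  }
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop_data("coordinates out of range or missing")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088 * 1000) / 1000
}

#' Tower-to-roost assignment settings
#'
#' @param pool_radius_km radius (km) within which several towers are
#'   understood to sample the same roost; pooling is implicit in the
#'   many-to-one nearest-roost mapping, so this value is descriptive
#'   metadata rather than an operative threshold. Default 20.
#' @param unknown_roost_threshold_km a tower farther than this from every
#'   known roost is taken to mark an unknown roost at the tower's own
#'   location. Default 25.
#' @return An object of class `assignment_config`.
#' @export
assignment_config <- function(pool_radius_km = 20,
                              unknown_roost_threshold_km = 25) {
  if (pool_radius_km < 0 || unknown_roost_threshold_km < 0) {
    stop_config("assignment radii must be nonnegative")
  }
  structure(list(pool_radius_km = pool_radius_km,
                 unknown_roost_threshold_km = unknown_roost_threshold_km),
            class = "assignment_config")
}

#' Read a tower coordinate table
#'
#' @param path CSV with columns `tower_id`, `lat`, `lon`.
#' @return `data.frame` of towers.
#' @export
read_towers <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tower_id", "lat", "lon")
  if (!all(need %in% names(t))) {
    stop_config("towers table needs columns: ", paste(need, collapse = ", "))
  }
  t$tower_id <- as.character(t$tower_id)
  t[need]
}

#' Read a roost-site table
#'
#' @param path CSV with columns `name`, `lat`, `lon` and optionally
#'   `provenance` (`known` or `inferred`; defaults to `known`).
#' @return `data.frame` of roost sites.
#' @export
read_roosts <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "lat", "lon")
  if (!all(need %in% names(r))) {
    stop_config("roosts table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(r$provenance)) r$provenance <- "known"
  if (anyDuplicated(r$name)) stop_data("roost names must be unique")
  r[c("name", "lat", "lon", "provenance")]
}

#' Assign each tower to a roost site
#'
#' Each tower maps to its nearest known roost when that roost is within
#' `unknown_roost_threshold_km`; several towers may pool onto one roost.
#' A tower farther than the threshold from every known roost spawns an
#' inferred roost at the tower's own coordinates (named after the tower)
#' and maps to it — overnight detections there are taken to indicate an
#' unknown roost in the vicinity.
#'
#' @param towers `data.frame` with `tower_id`, `lat`, `lon`.
#' @param roosts `data.frame` with `name`, `lat`, `lon` (known roost sites).
#' @param config an [assignment_config()].
#' @return An object of class `tower_assignment`: list with `mapping`
#'   (named character vector, tower_id -> roost name), `roosts` (the known
#'   plus inferred roost table) and `inferred` (names of inferred roosts).
#' @export
assign_towers <- function(towers, roosts, config = assignment_config()) {
  if (nrow(towers) == 0) stop_data("no towers to assign")
  known <- roosts[order(roosts$name), , drop = FALSE]
  mapping <- character(nrow(towers))
  inferred <- list()
  for (i in seq_len(nrow(towers))) {
    if (nrow(known) > 0) {
      d <- haversine_km(towers$lat[i], towers$lon[i], known$lat, known$lon)
      # known is name-sorted, so which.min's first-match breaks ties
      # lexicographically by roost name
      j <- which.min(d)
    }
    if (nrow(known) > 0 && d[j] <= config$unknown_roost_threshold_km) {
      mapping[i] <- known$name[j]
    } else {
      nm <- towers$tower_id[i]
      mapping[i] <- nm
      inferred[[nm]] <- data.frame(name = nm, lat = towers$lat[i],
                                   lon = towers$lon[i],
                                   provenance = "inferred",
                                   stringsAsFactors = FALSE)
    }
  }
  names(mapping) <- towers$tower_id
  all_roosts <- roosts
  if (is.null(all_roosts$provenance)) all_roosts$provenance <- "known"
  if (length(inferred) > 0) {
    all_roosts <- rbind(all_roosts[c("name", "lat", "lon", "provenance")],
                        do.call(rbind, inferred))
  }
  rownames(all_roosts) <- NULL
  structure(list(mapping = mapping, roosts = all_roosts,
                 inferred = names(inferred)),
            class = "tower_assignment")
}

#' @export
print.tower_assignment <- function(x, ...) {
  cat("Tower assignment: ", length(x$mapping), " towers -> ",
      length(unique(x$mapping)), " roosts (",
      length(x$inferred), " inferred)\n", sep = "")
  invisible(x)
}

#' Convert filtered detections to per-tag roost visit streams
#'
#' Groups detections by tag, sorts each group chronologically and replaces
#' tower ids with their assigned roost names.
#'
#' @param detections filtered detection `data.frame`.
#' @param assignment a [assign_towers()] result.
#' @return Named list (by `tag_id`, sorted) of character vectors of roost
#'   names in chronological order.
#' @export
detections_to_visits <- function(detections, assignment) {
  orphan <- setdiff(unique(detections$tower_id), names(assignment$mapping))
  if (length(orphan) > 0) {
    stop_data("detections at unassigned tower(s): ",
              paste(orphan, collapse = ", "))
  }
  if (nrow(detections) == 0) return(structure(list(), names = character()))
  detections <- detections[order(detections$tag_id, detections$timestamp), ]
  split(unname(assignment$mapping[detections$tower_id]), detections$tag_id)
}

#' Collapse consecutive repeats in a roost visit stream
#'
#' Repeat detections at the same roost are pooled into a single entry to
#' limit pseudoreplication; non-consecutive returns to a roost are kept.
#' Idempotent and never lengthens its input.
#'
#' @param visits character vector of roost names in chronological order.
#' @return The collapsed character vector.
#' @export
#' @examples
#' collapse_sequence(c("Caledonia", "Caledonia", "Bridgetown"))
collapse_sequence <- function(visits) {
  n <- length(visits)
  if (n <= 1) return(visits)
  visits[c(TRUE, visits[-1] != visits[-n])]
}

#' Build per-tag movement sequences from visit streams
#'
#' @param visits named list as returned by [detections_to_visits()].
#' @return Named list of collapsed movement sequences (one per tag).
#' @export
visits_to_sequences <- function(visits) {
  lapply(visits, collapse_sequence)
}

#' Summarise roost usage across tags
#'
#' Counts the distinct roosts each tag used and tabulates tags by that
#' count; also reports the share of tags that used more than one roost
#' (i.e. did not show roost-site fidelity).
#'
#' @param sequences named list of movement sequences.
#' @return List with `histogram` (named integer vector: distinct-roost
#'   count -> number of tags), `n_tags`, and `prop_multi_roost`.
#' @export
summarize_roost_usage <- function(sequences) {
  k <- vapply(sequences, function(s) length(unique(s)), integer(1))
  hist <- table(factor(k, levels = sort(unique(k))))
  out <- as.integer(hist)
  names(out) <- names(hist)
  list(histogram = out,
       n_tags = length(sequences),
       prop_multi_roost = if (length(k) == 0) NA_real_ else mean(k > 1))
}

#' Write movement sequences to CSV
#'
#' One row per tag: `tag_id` and the roosts joined in order with `";"`,
#' mirroring the one-row-per-bird layout of published movement tables.
#' [read_sequences()] parses the file back losslessly.
#'
#' @param sequences named list of movement sequences.
#' @param path output file path.
#' @export
write_sequences <- function(sequences, path) {
  df <- data.frame(tag_id = names(sequences),
                   roosts = vapply(sequences, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read movement sequences from CSV
#'
#' @param path file written by [write_sequences()].
#' @return Named list of movement sequences.
#' @export
read_sequences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  out <- strsplit(df$roosts, ";", fixed = TRUE)
  names(out) <- df$tag_id
  out
}
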