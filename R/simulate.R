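# Run body with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation settings for synthetic detection streams
#'
#' Describes a latent nightly roost-switching process (independent per-tag
#' Markov chains over roosts, all tags starting at the tagging site) and
#' the detection process that a Motus-style receiver array would record
#' from it: overnight detection runs at the tower nearest the occupied
#' roost, occasional short false-positive runs at random towers, and
#' daytime foraging detections outside the roosting window.
#'
#' @param roosts roost table (`name`, `lat`, `lon`).
#' @param towers tower table (`tower_id`, `lat`, `lon`).
#' @param switch_matrix row-stochastic roost-by-roost matrix of nightly
#'   transition probabilities, dimnames matching roost names.
#' @param tagging_site roost where every tag starts (first night).
#' @param n_tags number of tags (default 21, the study's tracked sample).
#' @param nights nights to simulate per tag (default 72, roughly
#'   late June through August).
#' @param detections_per_night mean number of detections in a true
#'   overnight run, one per 5-minute scan interval (default 12, one hour
#'   in range of the tower).
#' @param run_length_law function(n) drawing `n` integer run lengths >= 4
#'   for true runs; default `4 + rpois(n, detections_per_night - 4)`.
#' @param false_positive_rate expected short (run length 1-3) spurious runs
#'   per tag-night at a uniformly random tower (default 0.2).
#' @param foraging_rate expected daytime (out-of-window) detections per
#'   tag-day (default 1).
#' @param season_start first night's date (default `"2019-06-20"`).
#' @param tz time zone (default `"America/Halifax"`).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(roosts, towers, switch_matrix, tagging_site,
                       n_tags = 21L, nights = 72L,
                       detections_per_night = 12,
                       run_length_law = NULL,
                       false_positive_rate = 0.2,
                       foraging_rate = 1,
                       season_start = "2019-06-20",
                       tz = "America/Halifax",
                       seed = NULL) {
  nm <- roosts$name
  if (!is.matrix(switch_matrix) ||
      !identical(sort(rownames(switch_matrix)), sort(nm)) ||
      !identical(rownames(switch_matrix), colnames(switch_matrix))) {
    stop_config("switch_matrix must be a square matrix with roost-name dimnames")
  }
  if (any(switch_matrix < 0) ||
      any(abs(rowSums(switch_matrix) - 1) > 1e-8)) {
    stop_config("switch_matrix rows must be nonnegative and sum to 1")
  }
  if (!tagging_site %in% nm) stop_config("tagging_site must be a roost name")
  if (false_positive_rate < 0 || foraging_rate < 0) {
    stop_config("rates must be nonnegative")
  }
  if (is.null(run_length_law)) {
    lambda <- max(detections_per_night - 4, 0)
    run_length_law <- function(n) 4L + stats::rpois(n, lambda)
  }
  structure(list(roosts = roosts, towers = towers,
                 switch_matrix = switch_matrix, tagging_site = tagging_site,
                 n_tags = as.integer(n_tags), nights = as.integer(nights),
                 detections_per_night = detections_per_night,
                 run_length_law = run_length_law,
                 false_positive_rate = false_positive_rate,
                 foraging_rate = foraging_rate,
                 season_start = as.Date(season_start), tz = tz, seed = seed),
            class = "sim_config")
}

#' Simulate latent roost-occupancy tracks
#'
#' Draws one nightly roost-occupancy sequence per tag from the configured
#' Markov chain; every tag's first night is at the tagging site.
#' Reproducible under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return Named list (tag id `"t01"`, `"t02"`, ...) of character vectors,
#'   one roost name per night.
#' @export
simulate_tracks <- function(config) {
  with_local_seed(config$seed, {
    states <- rownames(config$switch_matrix)
    lapply(stats::setNames(seq_len(config$n_tags),
                           sprintf("t%02d", seq_len(config$n_tags))),
           function(i) {
             s <- character(config$nights)
             s[1] <- config$tagging_site
             for (k in seq_len(config$nights - 1)) {
               s[k + 1] <- sample(states, 1,
                                  prob = config$switch_matrix[s[k], ])
             }
             s
           })
  })
}

# Inverse of the nearest-roost rule: for each roost, the assigned tower
# closest to it (towers map to roosts via assign_towers).
roost_to_tower <- function(config) {
  assignment <- assign_towers(config$towers, config$roosts)
  occupied <- config$roosts$name
  out <- character(length(occupied))
  names(out) <- occupied
  for (r in occupied) {
    cand <- names(assignment$mapping)[assignment$mapping == r]
    if (length(cand) == 0) next
    i <- match(cand, config$towers$tower_id)
    d <- haversine_km(config$roosts$lat[match(r, config$roosts$name)],
                      config$roosts$lon[match(r, config$roosts$name)],
                      config$towers$lat[i], config$towers$lon[i])
    out[r] <- cand[which.min(d)]
  }
  out
}

#' Emit synthetic detections from latent tracks
#'
#' For each tag-night, emits one true detection run (length drawn from
#' `run_length_law`, so always > 3) at the tower nearest the occupied
#' roost, with 5-minute-interval timestamps inside the evening part of the
#' 18:00–10:00 roosting window; Poisson-distributed false-positive runs of
#' length 1–3 at uniformly random towers (also inside the window, so only
#' the run-length filter can remove them); and Poisson-distributed daytime
#' foraging detections outside the window. With both noise rates zero,
#' every emitted detection survives all three detection filters.
#'
#' @param tracks result of [simulate_tracks()].
#' @param config the same [sim_config()].
#' @return Detection `data.frame` (as from [read_detections()]), sorted by
#'   tag and timestamp.
#' @export
emit_detections <- function(tracks, config) {
  r2t <- roost_to_tower(config)
  occupied <- unique(unlist(tracks, use.names = FALSE))
  missing <- occupied[r2t[occupied] == "" | is.na(r2t[occupied])]
  if (length(missing) > 0) {
    stop_data("no tower maps to occupied roost(s): ",
              paste(missing, collapse = ", "))
  }
  # offset the seed so the emission stream is independent of the track draw
  with_local_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    rows <- list()
    push <- function(tag, t0, tower, len, spacing = 300) {
      rows[[length(rows) + 1]] <<- new_detections(
        tag, t0 + spacing * (seq_len(len) - 1), tower, len)
    }
    night0 <- as.POSIXct(paste(format(config$season_start), "00:00:00"),
                         tz = config$tz)
    for (tag in names(tracks)) {
      occ <- tracks[[tag]]
      for (k in seq_along(occ)) {
        base <- night0 + (k - 1) * 86400
        # true overnight run: starts 18:00-21:00, 5-min intervals
        len <- config$run_length_law(1)
        start <- base + 18 * 3600 + stats::runif(1, 0, 3 * 3600)
        push(tag, start, r2t[[occ[k]]], len)
        # false-positive short runs
        n_fp <- stats::rpois(1, config$false_positive_rate)
        for (f in seq_len(n_fp)) {
          push(tag, base + 18 * 3600 + stats::runif(1, 0, 3 * 3600),
               sample(config$towers$tower_id, 1), sample(3, 1))
        }
        # daytime foraging detections (outside the window)
        n_fo <- stats::rpois(1, config$foraging_rate)
        for (f in seq_len(n_fo)) {
          push(tag, base + 10 * 3600 + stats::runif(1, 0, 8 * 3600 - 60),
               sample(config$towers$tower_id, 1), config$run_length_law(1))
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$tag_id, out$timestamp), ]
    rownames(out) <- NULL
    out
  })
}

#' Default synthetic study geometry and configuration
#'
#' Builds a ready-to-run [sim_config()] emulating the study's setting:
#' `n_roosts` roost sites spread across a southern-Nova-Scotia-sized
#' extent, one tower within ~2 km of each roost so nearest-roost
#' assignment is unambiguous ("easy" geometry), and a sticky Markov chain
#' (stay probability `p_stay`, remainder uniform over the other roosts).
#' With `hard_mode = TRUE` the geometry also exercises the assignment
#' edge cases: two extra towers pool onto the first roost and one remote
#' tower (>25 km from every roost) spawns an inferred roost.
#'
#' @param n_roosts number of roost sites (default 10).
#' @param p_stay nightly probability of staying at the current roost
#'   (default 0.6).
#' @param hard_mode add pooling and far-away towers (default `FALSE`).
#' @param ... passed on to [sim_config()] (e.g. `n_tags`, `nights`,
#'   `seed`, noise rates).
#' @return A `sim_config`.
#' @export
synthetic_study <- function(n_roosts = 10, p_stay = 0.6,
                            hard_mode = FALSE, ...) {
  name <- sprintf("Roost%02d", seq_len(n_roosts))
  # deterministic pseudo-random spread over ~1.2 x 1.6 degrees
  i <- seq_len(n_roosts)
  lat <- 43.7 + ((i * 7) %% n_roosts) / n_roosts * 1.2
  lon <- -65.9 + ((i * 3) %% n_roosts) / n_roosts * 1.6
  roosts <- data.frame(name = name, lat = lat, lon = lon,
                       provenance = "known", stringsAsFactors = FALSE)
  towers <- data.frame(tower_id = sprintf("tower_%02d", i),
                       lat = lat + 0.015, lon = lon + 0.01,
                       stringsAsFactors = FALSE)
  if (hard_mode) {
    towers <- rbind(towers, data.frame(
      tower_id = c("tower_pool_a", "tower_pool_b", "tower_remote"),
      lat = c(lat[1] + 0.05, lat[1] - 0.06, 46.9),
      lon = c(lon[1] + 0.05, lon[1] - 0.05, -64.0)))
  }
  m <- matrix((1 - p_stay) / (n_roosts - 1), n_roosts, n_roosts,
              dimnames = list(name, name))
  diag(m) <- p_stay
  sim_config(roosts = roosts, towers = towers, switch_matrix = m,
             tagging_site = name[1], ...)
}

#' Write latent tracks as ground-truth CSV
#'
#' @param tracks result of [simulate_tracks()].
#' @param path output file path.
#' @export
write_tracks <- function(tracks, path) {
  df <- data.frame(tag_id = rep(names(tracks), lengths(tracks)),
                   night = unlist(lapply(tracks, seq_along)),
                   roost = unlist(tracks, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
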