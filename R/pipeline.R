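#' Pipeline configuration
#'
#' Collects the paths and parameters for an end-to-end run. Either
#' `sequences` (a pre-built movement-sequence CSV, skipping the telemetry
#' stages) or all three of `detections`, `towers` and `roosts` must be
#' supplied.
#'
#' @param out_dir output directory (created if needed).
#' @param detections,towers,roosts input CSV paths for the telemetry route.
#' @param sequences movement-sequence CSV path (see [write_sequences()]).
#' @param filter a [filter_config()].
#' @param assignment an [assignment_config()].
#' @param tagging_site roost name where tags were deployed, or `NULL`.
#' @param removals roosts to knock out; `NULL` selects the union of the
#'   top-`top_k` roosts by degree and by closeness.
#' @param top_k how many top roosts per measure when `removals` is `NULL`
#'   (default 3).
#' @param test_values `"raw"` or `"rounded"`, see [knockout_analysis()].
#' @param plot_seed seed for the network plot layout (default 1).
#' @param verbose log stage progress (default `TRUE`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            detections = NULL, towers = NULL, roosts = NULL,
                            sequences = NULL,
                            filter = filter_config(),
                            assignment = assignment_config(),
                            tagging_site = NULL,
                            removals = NULL, top_k = 3,
                            test_values = "raw",
                            plot_seed = 1,
                            verbose = TRUE) {
  if (is.null(sequences) &&
      (is.null(detections) || is.null(towers) || is.null(roosts))) {
    stop_config("supply either `sequences` or all of `detections`, `towers`, `roosts`")
  }
  for (p in c(detections, towers, roosts, sequences)) {
    if (!file.exists(p)) stop_config("input file not found: ", p)
  }
  structure(list(out_dir = out_dir, detections = detections, towers = towers,
                 roosts = roosts, sequences = sequences, filter = filter,
                 assignment = assignment, tagging_site = tagging_site,
                 removals = removals, top_k = top_k,
                 test_values = test_values, plot_seed = plot_seed,
                 verbose = verbose),
            class = "pipeline_config")
}

pipeline_provenance <- function(config) {
  hashable <- config
  hashable$filter$season_cutoff <- format(hashable$filter$season_cutoff)
  list(package = "roostnet",
       version = as.character(utils::packageVersion("roostnet")),
       config_hash = config_hash(hashable))
}

prepend_header <- function(path, provenance) {
  lines <- readLines(path)
  writeLines(c(sprintf("# roostnet %s config %s", provenance$version,
                       provenance$config_hash), lines), path)
}

#' Run the full roost-network pipeline
#'
#' Filters detections, assigns towers to roosts, derives collapsed
#' movement sequences, builds the multigraph, computes centralities and
#' communities, performs the knockout analysis, and writes all artifacts
#' to `config$out_dir`: `sequences.csv`, `edges.csv`, `network.graphml`,
#' `centrality.csv`, `usage.json`, `communities.json`, `knockout.csv`,
#' `knockout.json`, `network.png` (+ layout sidecar `network_layout.json`),
#' `provenance.json` and `run.log`. CSV artifacts carry a one-line
#' provenance comment (`# roostnet <version> config <hash>`). Outputs are
#' deterministic for fixed inputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory `sequences`, `network`,
#'   `centrality`, `usage`, `communities`, `knockout` and `provenance`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (config$verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  provenance <- pipeline_provenance(config)

  if (!is.null(config$sequences)) {
    seqs <- stage("sequences", read_sequences(config$sequences))
    say("loaded ", length(seqs), " movement sequences")
  } else {
    det <- stage("read", read_detections(config$detections,
                                         tz = config$filter$tz))
    say("read ", nrow(det), " detections")
    n0 <- nrow(det)
    det <- stage("filter", filter_detections(det, config$filter))
    say("filters kept ", nrow(det), " of ", n0, " detections")
    towers <- stage("towers", read_towers(config$towers))
    roosts <- stage("roosts", read_roosts(config$roosts))
    assignment <- stage("assign",
                        assign_towers(towers, roosts, config$assignment))
    say("assigned ", length(assignment$mapping), " towers to ",
        length(unique(assignment$mapping)), " roosts (",
        length(assignment$inferred), " inferred)")
    visits <- stage("visits", detections_to_visits(det, assignment))
    seqs <- stage("collapse", visits_to_sequences(visits))
    say("derived ", length(seqs), " movement sequences")
  }

  net <- stage("network", build_network(seqs, config$tagging_site))
  say("network: ", length(net$nodes), " roosts, ", nrow(net$edges), " links")
  usage <- summarize_roost_usage(seqs)
  cent <- stage("centrality", centrality_table(net))
  comm <- stage("communities", detect_communities(net))
  removals <- config$removals
  if (is.null(removals)) {
    removals <- union(select_key_roosts(cent, config$top_k, "degree"),
                      select_key_roosts(cent, config$top_k, "closeness"))
  }
  say("knockout removals: ", paste(removals, collapse = ", "))
  ko <- stage("knockout", knockout_analysis(net, removals,
                                            values = config$test_values))

  out <- function(f) file.path(config$out_dir, f)
  write_sequences(seqs, out("sequences.csv"))
  write_edgelist(net, out("edges.csv"))
  write_graphml(net, out("network.graphml"))
  utils::write.csv(cent, out("centrality.csv"), row.names = FALSE)
  write_knockout_csv(ko, out("knockout.csv"))
  write_knockout_json(ko, out("knockout.json"))
  jsonlite::write_json(list(provenance = provenance,
                            histogram = as.list(stats::setNames(
                              as.integer(usage$histogram),
                              names(usage$histogram))),
                            n_tags = usage$n_tags,
                            prop_multi_roost = usage$prop_multi_roost),
                       out("usage.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(provenance = provenance,
                            membership = as.list(comm$membership),
                            modularity = comm$modularity),
                       out("communities.json"), auto_unbox = TRUE, digits = NA)
  render_network_plot(net, comm, out("network.png"), seed = config$plot_seed)
  for (f in c("sequences.csv", "edges.csv", "centrality.csv", "knockout.csv")) {
    prepend_header(out(f), provenance)
  }
  jsonlite::write_json(provenance, out("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, logfile)
  invisible(list(sequences = seqs, network = net, centrality = cent,
                 usage = usage, communities = comm, knockout = ko,
                 provenance = provenance))
}

#' Plot the roost network coloured by community
#'
#' Static PNG of the simple projection with link multiplicity as edge
#' width and nodes coloured by community membership. The layout is
#' force-directed with a fixed seed; the exact node coordinates are
#' exported to a JSON sidecar (`<path> without extension + "_layout.json"`)
#' so layout determinism can be verified without comparing image bytes.
#'
#' @param network a `roost_network`.
#' @param partition optional [detect_communities()] result.
#' @param path output PNG path.
#' @param seed layout seed (default 1).
#' @return Invisibly, the sidecar JSON path.
#' @export
render_network_plot <- function(network, partition = NULL, path,
                                seed = 1) {
  g <- as_igraph(network, simplify = TRUE)
  set.seed(seed)
  coords <- igraph::layout_with_fr(g)
  memb <- if (is.null(partition)) rep(1L, length(network$nodes)) else {
    as.integer(partition$membership[igraph::V(g)$name])
  }
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(max(memb, 1L), "Dark 3")
  igraph::plot.igraph(
    g, layout = coords,
    vertex.color = pal[memb],
    vertex.label.color = "black",
    vertex.size = 18,
    edge.width = if (igraph::ecount(g) > 0) igraph::E(g)$weight else 1
  )
  sidecar <- paste0(sub("\\.[A-Za-z]+$", "", path), "_layout.json")
  jsonlite::write_json(
    list(seed = seed,
         nodes = igraph::V(g)$name,
         x = coords[, 1], y = coords[, 2],
         membership = memb),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
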