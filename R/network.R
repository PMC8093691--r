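#' Build the roost movement multigraph
#'
#' Each consecutive pair of roosts in a tag's collapsed movement sequence
#' contributes one undirected edge, tagged with the contributing tag id.
#' Because every bird was captured at a single tagging site, a sequence's
#' first transition is dropped when it departs that site: the initial
#' departure is an artefact of where tagging happened, and the tagging site
#' earns links only through returns and subsequent movements. Self-loops are
#' dropped defensively (collapsed input cannot produce them). Nodes include
#' every roost appearing in any sequence, including isolated ones.
#'
#' @param sequences named list of collapsed movement sequences
#'   (no consecutive duplicate roosts; see [collapse_sequence()]).
#' @param tagging_site roost name where all tags were deployed, or `NULL`
#'   to disable the first-transition correction.
#' @return An object of class `roost_network`: list with `nodes` (sorted
#'   character), `edges` (`data.frame` with `from`, `to`, `tag_id`; endpoint
#'   pairs stored in lexicographic order) and `tagging_site`.
#' @export
build_network <- function(sequences, tagging_site = NULL) {
  for (tag in names(sequences)) {
    s <- sequences[[tag]]
    if (length(s) > 1 && any(s[-1] == s[-length(s)])) {
      stop_data("sequence for tag ", tag,
                " has consecutive duplicate roosts; collapse it first")
    }
  }
  from <- character(0); to <- character(0); tag_of <- character(0)
  for (tag in names(sequences)) {
    s <- sequences[[tag]]
    if (length(s) < 2) next
    a <- s[-length(s)]
    b <- s[-1]
    if (!is.null(tagging_site) && s[1] == tagging_site) {
      a <- a[-1]; b <- b[-1]
    }
    keep <- a != b  # defensive: no loops
    from <- c(from, pmin(a[keep], b[keep]))
    to <- c(to, pmax(a[keep], b[keep]))
    tag_of <- c(tag_of, rep(tag, sum(keep)))
  }
  nodes <- sort(unique(c(unlist(sequences, use.names = FALSE), from, to)))
  edges <- data.frame(from = from, to = to, tag_id = tag_of,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$tag_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, tagging_site = tagging_site),
            class = "roost_network")
}

#' @export
print.roost_network <- function(x, ...) {
  cat("Roost network: ", length(x$nodes), " roosts, ", nrow(x$edges),
      " links (multigraph)\n", sep = "")
  if (!is.null(x$tagging_site)) {
    cat("  tagging site: ", x$tagging_site, "\n", sep = "")
  }
  invisible(x)
}

#' Convert a roost network to an igraph object
#'
#' @param network a `roost_network`.
#' @param simplify if `TRUE`, return the simple projection (parallel edges
#'   merged, multiplicity kept as the `weight` edge attribute); if `FALSE`
#'   (default) keep the multigraph.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network, simplify = FALSE) {
  g <- igraph::graph_from_data_frame(network$edges[c("from", "to")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  if (simplify) {
    igraph::E(g)$weight <- 1
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
  }
  g
}

#' Degree centrality (max-normalised multigraph degree)
#'
#' A roost's raw degree is its incident link count with multiplicity
#' (every recorded movement counts); degree centrality is the raw degree
#' expressed as a proportion of the greatest raw degree in the network,
#' so the best-connected roost(s) score exactly 1.
#'
#' @param network a `roost_network` with at least one edge. An edgeless
#'   network yields all-zero centralities with attribute `edgeless = TRUE`.
#' @return `data.frame` with columns `roost`, `raw_degree`,
#'   `degree_centrality`, in node order.
#' @export
degree_centrality <- function(network) {
  g <- as_igraph(network)
  deg <- igraph::degree(g, loops = FALSE)
  out <- data.frame(roost = network$nodes,
                    raw_degree = as.integer(deg[network$nodes]),
                    stringsAsFactors = FALSE)
  if (max(out$raw_degree) == 0) {
    out$degree_centrality <- 0
    attr(out, "edgeless") <- TRUE
  } else {
    out$degree_centrality <- out$raw_degree / max(out$raw_degree)
  }
  rownames(out) <- NULL
  out
}

#' Shortest-path step distances between roosts
#'
#' Breadth-first (unweighted) distances on the simple projection of the
#' network: parallel links count once, and a step is one link regardless of
#' geography. Pairs with no connecting path are assigned a sentinel distance
#' equal to the current node count, so isolated roosts receive a finite,
#' comparably poor closeness instead of an undefined one.
#'
#' @param network a `roost_network`.
#' @return Integer matrix of step distances, rows and columns in node order.
#' @export
shortest_path_distances <- function(network) {
  g <- as_igraph(network, simplify = TRUE)
  d <- igraph::distances(g, mode = "all", weights = NA)
  d <- d[network$nodes, network$nodes, drop = FALSE]
  d[is.infinite(d)] <- length(network$nodes)
  storage.mode(d) <- "integer"
  d
}

#' Closeness centrality (reciprocal distance sum)
#'
#' A roost's closeness is the reciprocal of the sum of its shortest-path
#' step distances to every other roost (see
#' [shortest_path_distances()] for the unreachable-pair sentinel). Values
#' are raw reciprocals, not normalised.
#'
#' @param network a `roost_network` with at least two nodes.
#' @return `data.frame` with columns `roost`, `distance_sum`, `closeness`,
#'   in node order.
#' @export
closeness_centrality <- function(network) {
  if (length(network$nodes) < 2) {
    stop_data("closeness undefined for a network with fewer than 2 roosts")
  }
  d <- shortest_path_distances(network)
  ds <- rowSums(d)  # diagonal is 0
  data.frame(roost = network$nodes,
             distance_sum = as.integer(ds),
             closeness = 1 / ds,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Full centrality table for a network
#'
#' Joins [degree_centrality()] and [closeness_centrality()] into one table.
#'
#' @param network a `roost_network`.
#' @return `data.frame` with columns `roost`, `raw_degree`,
#'   `degree_centrality`, `distance_sum`, `closeness`.
#' @export
centrality_table <- function(network) {
  cbind(degree_centrality(network),
        closeness_centrality(network)[c("distance_sum", "closeness")])
}

#' Remove a roost from the network
#'
#' Deletes the node and all its incident links; no rerouting or sequence
#' re-derivation is performed, and remaining roosts are kept even if the
#' removal isolates them.
#'
#' @param network a `roost_network`.
#' @param roost name of the roost to remove.
#' @return The reduced `roost_network`.
#' @export
remove_roost <- function(network, roost) {
  if (!roost %in% network$nodes) {
    stop_data("roost not in network: ", roost)
  }
  edges <- network$edges
  edges <- edges[edges$from != roost & edges$to != roost, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = setdiff(network$nodes, roost), edges = edges,
                 tagging_site = network$tagging_site),
            class = "roost_network")
}

#' Detect roost communities
#'
#' Groups roosts that share more links with each other than with the rest
#' of the network, by divisive clustering: edges of maximum betweenness are
#' removed iteratively (Girvan–Newman) and the dendrogram is cut at maximum
#' modularity, computed on the multigraph so repeated movements weigh in.
#' Deterministic for a given network (edges are held in lexicographic
#' order); singleton communities are allowed.
#'
#' @param network a `roost_network` with at least one node.
#' @return List with `membership` (named integer vector node -> community
#'   label) and `modularity` (the partition's modularity score).
#' @export
detect_communities <- function(network) {
  if (length(network$nodes) < 1) stop_data("empty network")
  g <- as_igraph(network)
  if (nrow(network$edges) == 0) {
    memb <- seq_along(network$nodes)
    names(memb) <- network$nodes
    return(list(membership = memb, modularity = NA_real_))
  }
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL, directed = FALSE)
  memb <- igraph::membership(cl)
  out <- as.integer(memb[network$nodes])
  names(out) <- network$nodes
  list(membership = out, modularity = max(cl$modularity))
}

#' Write the network edge list to CSV
#'
#' One row per distinct (roost pair, tag) combination with its
#' multiplicity, so the multigraph reconstructs exactly.
#'
#' @param network a `roost_network`.
#' @param path output file path.
#' @export
write_edgelist <- function(network, path) {
  e <- network$edges
  if (nrow(e) == 0) {
    agg <- data.frame(roost_a = character(), roost_b = character(),
                      tag_id = character(), multiplicity = integer())
  } else {
    agg <- stats::aggregate(list(multiplicity = rep(1L, nrow(e))),
                            by = list(roost_a = e$from, roost_b = e$to,
                                      tag_id = e$tag_id),
                            FUN = sum)
    agg <- agg[order(agg$roost_a, agg$roost_b, agg$tag_id), ]
  }
  utils::write.csv(agg, path, row.names = FALSE)
  invisible(path)
}

#' Export the simple projection as GraphML
#'
#' Parallel links are merged; the merged edge carries its multiplicity as
#' the `weight` attribute.
#'
#' @param network a `roost_network`.
#' @param path output file path.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network, simplify = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
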