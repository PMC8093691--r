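# Independent oracles and small fixture builders shared across tests.

# Build a detection table directly (timestamps given as strings, Halifax time).
make_det <- function(ts, tag = "t1", tower = "tw1", run = 10L,
                     tz = "America/Halifax") {
  data.frame(tag_id = rep_len(as.character(tag), length(ts)),
             timestamp = as.POSIXct(ts, tz = tz),
             tower_id = rep_len(as.character(tower), length(ts)),
             run_length = rep_len(as.integer(run), length(ts)),
             stringsAsFactors = FALSE)
}

# Construct a roost_network directly from an edge data.frame (for graph
# oracle tests that bypass sequence building).
make_network <- function(edges, nodes = NULL) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- data.frame(from = a, to = b,
                      tag_id = edges$tag_id %||% rep("t", length(a)),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, tagging_site = NULL),
            class = "roost_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force multigraph degree: count endpoint occurrences.
bf_degree <- function(network) {
  ends <- c(network$edges$from, network$edges$to)
  vapply(network$nodes, function(v) sum(ends == v), integer(1))
}

# Brute-force unweighted distances by iterated adjacency-matrix expansion
# (independent of igraph's BFS); unreachable -> node count.
bf_distances <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(network$edges))) {
    A[network$edges$from[i], network$edges$to[i]] <- 1
    A[network$edges$to[i], network$edges$from[i]] <- 1
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  R <- diag(n)
  P <- diag(n)
  for (step in seq_len(n)) {
    P <- (P %*% A > 0) * 1
    newly <- P > 0 & !(R > 0)
    D[newly] <- step
    R <- ((R + P) > 0) * 1
  }
  D[is.infinite(D)] <- n
  D
}

# Random small multigraph for oracle-equivalence property tests.
random_multigraph <- function(n_nodes, n_edges) {
  nodes <- LETTERS[seq_len(n_nodes)]
  if (n_edges == 0) {
    return(make_network(data.frame(from = character(), to = character(),
                                   stringsAsFactors = FALSE),
                        nodes = nodes))
  }
  pairs <- t(replicate(n_edges, sample(nodes, 2)))
  make_network(data.frame(from = pairs[, 1], to = pairs[, 2],
                          stringsAsFactors = FALSE),
               nodes = nodes)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (Pratt ranking: ranks of |d| computed with zeros included, zero ranks
# then held out of every W+). Uses the mid-p convention — half weight on
# the observed point of the discrete permutation distribution — which is
# the appropriate yardstick for a continuous (normal) approximation; the
# uncorrected normal p then provably sits within 0.02 of it for n >= 9.
exact_signed_rank_p <- function(before, after) {
  d <- before - after
  r <- rank(abs(d))
  nz <- which(d != 0)
  k <- length(nz)
  n <- length(d)
  m <- n - k
  e_w <- (n * (n + 1) - m * (m + 1)) / 4
  obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), k))
  w <- as.matrix(signs) %*% r[nz]
  p_geq <- mean(abs(w - e_w) >= abs(obs - e_w) - 1e-12)
  p_gt <- mean(abs(w - e_w) > abs(obs - e_w) + 1e-12)
  (p_geq + p_gt) / 2
}

# Closed-form z for n all-one-sign pairs, distinct |d|, no zeros.
all_one_sign_z <- function(n, positive = TRUE) {
  w <- if (positive) n * (n + 1) / 2 else 0
  (w - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
}

# Printed full-network golden column (degree at 2 dp, closeness at 3 dp).
table2_all_sites <- function() {
  data.frame(
    roost = c("Blandford", "Bridgetown", "Caledonia", "Jordan Bay",
              "Liverpool", "Marshalltown", "Middleton", "Upper Clements",
              "Weymouth", "Wolfville"),
    degree = c(0.18, 0.73, 1.00, 0.09, 0.09, 0.45, 0.36, 0.82, 0.36, 0.27),
    closeness = c(0.056, 0.059, 0.077, 0.040, 0.042, 0.063, 0.040, 0.063,
                  0.059, 0.059),
    stringsAsFactors = FALSE
  )
}
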