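test_that("network construction applies the tagging-site rule and drops loops", {
  # a bird that only departed the tagging site contributes no link
  net1 <- build_network(list("247" = c("Caledonia", "Bridgetown")),
                        tagging_site = "Caledonia")
  expect_equal(nrow(net1$edges), 0)
  expect_equal(net1$nodes, c("Bridgetown", "Caledonia"))

  # later transitions (including post-return departures) all count
  net2 <- build_network(
    list("628" = c("Caledonia", "Upper Clements", "Caledonia", "Blandford",
                   "Upper Clements", "Caledonia", "Weymouth")),
    tagging_site = "Caledonia")
  expect_equal(nrow(net2$edges), 5)
  got <- paste(net2$edges$from, net2$edges$to, sep = "--")
  expect_equal(sort(got),
               sort(c("Caledonia--Upper Clements", "Blandford--Caledonia",
                      "Blandford--Upper Clements", "Caledonia--Upper Clements",
                      "Caledonia--Weymouth")))

  # without a tagging site the first transition counts too
  expect_equal(nrow(build_network(list(a = c("X", "Y")))$edges), 1)

  # uncollapsed input is rejected with the offending tag
  expect_error(build_network(list(bad = c("A", "A", "B"))), "bad",
               class = "roostnet_data_error")

  # full fixture: 10 roosts, 24 links
  full <- build_network(table1_fixture(), "Caledonia")
  expect_equal(length(full$nodes), 10)
  expect_equal(nrow(full$edges), 24)
})

test_that("degree centrality is multigraph degree over the maximum", {
  net <- build_network(table1_fixture(), "Caledonia")
  deg <- degree_centrality(net)
  expect_equal(deg$degree_centrality[deg$roost == "Caledonia"], 1.0)
  expect_equal(deg$raw_degree[deg$roost == "Caledonia"], 11L)
  expect_equal(deg$degree_centrality[deg$roost == "Upper Clements"], 9 / 11)
  expect_equal(sum(deg$degree_centrality == 1), 1)

  two <- make_network(data.frame(from = "A", to = "B"))
  expect_equal(degree_centrality(two)$degree_centrality, c(1, 1))

  lone <- make_network(data.frame(from = character(), to = character()),
                       nodes = c("A", "B"))
  d0 <- degree_centrality(lone)
  expect_equal(d0$degree_centrality, c(0, 0))
  expect_true(attr(d0, "edgeless"))
})

test_that("step distances use the simple projection with a node-count sentinel", {
  path3 <- make_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  d <- shortest_path_distances(path3)
  expect_equal(d["A", "C"], 2L)
  expect_equal(diag(d), c(A = 0L, B = 0L, C = 0L))
  expect_equal(d, t(d))

  # an isolated node in a 9-node network sits at sentinel distance 9
  iso <- make_network(
    data.frame(from = LETTERS[1:7], to = LETTERS[c(2:7, 1)]),
    nodes = LETTERS[1:9])
  d9 <- shortest_path_distances(iso)
  expect_equal(unname(d9["I", setdiff(LETTERS[1:9], "I")]), rep(9L, 8))

  # fixture: Caledonia reaches everything within 2 steps, sum 13
  net <- build_network(table1_fixture(), "Caledonia")
  dsum <- rowSums(shortest_path_distances(net))
  expect_equal(unname(dsum["Caledonia"]), 13)
})

test_that("closeness is the reciprocal distance sum, matching the printed network", {
  net <- build_network(table1_fixture(), "Caledonia")
  clo <- closeness_centrality(net)
  expect_equal(round_half_up(clo$closeness[clo$roost == "Caledonia"], 3), 0.077)
  expect_equal(round_half_up(clo$closeness[clo$roost == "Blandford"], 3), 0.056)
  # distance sums are integers, so 1/closeness must be integral
  expect_equal(1 / clo$closeness, round(1 / clo$closeness))

  nb <- remove_roost(net, "Bridgetown")
  cnb <- closeness_centrality(nb)
  expect_equal(round_half_up(cnb$closeness[cnb$roost == "Middleton"], 3), 0.014)

  single <- make_network(data.frame(from = character(), to = character()),
                         nodes = "A")
  expect_error(closeness_centrality(single), class = "roostnet_data_error")
})

test_that("roost removal deletes incident links without rerouting", {
  net <- build_network(table1_fixture(), "Caledonia")
  nb <- remove_roost(net, "Bridgetown")
  expect_false("Bridgetown" %in% nb$nodes)
  expect_equal(degree_centrality(nb)$raw_degree[nb$nodes == "Middleton"], 0L)
  # Middleton is kept although isolated
  expect_true("Middleton" %in% nb$nodes)

  nm <- remove_roost(net, "Marshalltown")
  dm <- degree_centrality(nm)
  expect_equal(dm$degree_centrality[dm$roost == "Bridgetown"], 8 / 11)

  expect_error(remove_roost(net, "Foo"), class = "roostnet_data_error")
})

test_that("degree and distances agree with brute-force oracles on random multigraphs", {
  set.seed(99)
  for (i in 1:30) {
    net <- random_multigraph(sample(2:8, 1), sample(0:12, 1))
    deg <- degree_centrality(net)
    expect_equal(deg$raw_degree, unname(bf_degree(net)))
    expect_equal(shortest_path_distances(net), bf_distances(net),
                 ignore_attr = FALSE)
    # removal subtraction identity: degree drops by the multiplicity of
    # edges shared with the removed node
    v <- sample(net$nodes, 1)
    red <- remove_roost(net, v)
    mult <- vapply(red$nodes, function(u) {
      sum((net$edges$from == u & net$edges$to == v) |
            (net$edges$from == v & net$edges$to == u))
    }, numeric(1))
    expect_equal(degree_centrality(red)$raw_degree,
                 unname(bf_degree(net)[red$nodes] - mult))
  }
})

test_that("community detection finds obvious structure and connected groups", {
  tri2 <- make_network(data.frame(
    from = c("A", "B", "C", "X", "Y", "Z"),
    to = c("B", "C", "A", "Y", "Z", "X")))
  expect_equal(length(unique(detect_communities(tri2)$membership)), 2)

  k4 <- make_network(data.frame(from = c("A", "A", "A", "B", "B", "C"),
                                to = c("B", "C", "D", "C", "D", "D")))
  expect_equal(length(unique(detect_communities(k4)$membership)), 1)

  net <- build_network(table1_fixture(), "Caledonia")
  part <- detect_communities(net)
  expect_setequal(names(part$membership), net$nodes)
  # every community must induce a connected subgraph
  for (g in unique(part$membership)) {
    members <- names(part$membership)[part$membership == g]
    sub <- make_network(net$edges[net$edges$from %in% members &
                                    net$edges$to %in% members, , drop = FALSE],
                        nodes = members)
    d <- bf_distances(sub)
    expect_true(all(d[members, members] < length(members) + 1) ||
                  length(members) == 1)
  }
  # at least as many communities as connected components
  comp_sentinel <- shortest_path_distances(net) == length(net$nodes)
  n_comp <- length(unique(apply(comp_sentinel, 1, paste, collapse = "")))
  expect_gte(length(unique(part$membership)), n_comp)
})

test_that("edge list and GraphML exports preserve the multigraph", {
  net <- build_network(table1_fixture(), "Caledonia")
  f <- withr::local_tempfile(fileext = ".csv")
  write_edgelist(net, f)
  el <- utils::read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
  expect_equal(sum(el$multiplicity), nrow(net$edges))

  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(back), 10)
  expect_equal(sum(igraph::E(back)$weight), 24)
})
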