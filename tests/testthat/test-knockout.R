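test_that("signed-rank test matches the all-one-sign closed form", {
  # 9 pairs, all after > before, distinct magnitudes, no zeros:
  # W+ = 0, E = 22.5, Var = 71.25
  before <- 1:9
  after <- before + (1:9) / 10
  res <- wilcoxon_pratt(before, after)
  expect_equal(res$w_plus, 0)
  expect_equal(res$expectation, 22.5)
  expect_equal(res$variance, 71.25)
  expect_equal(res$z, -22.5 / sqrt(71.25), tolerance = 1e-12)
  expect_equal(res$z, all_one_sign_z(9, positive = FALSE))
  expect_equal(round(abs(res$z), 4), 2.6656)

  # swapping before/after negates z
  flip <- wilcoxon_pratt(after, before)
  expect_equal(flip$z, -res$z)
  expect_equal(flip$p_two_sided, res$p_two_sided)
})

test_that("signed-rank test handles zeros (Pratt) and ties", {
  # zeros are ranked, then dropped from W+
  res <- wilcoxon_pratt(c(5, 5, 5, 1, 2), c(5, 5, 5, 3, 1))
  # |d| = 0,0,0,2,1 -> ranks 2,2,2,5,4; W+ = 4
  expect_equal(res$n_zero, 3)
  expect_equal(res$w_plus, 4)
  expect_equal(res$expectation, (5 * 6 - 3 * 4) / 4)

  # tied nonzero magnitudes reduce the variance by sum(t^3 - t)/48
  tied <- wilcoxon_pratt(c(1, 1, 4, 9), c(2, 2, 2, 2))
  expect_equal(tied$variance, (4 * 5 * 9) / 24 - (8 - 2) / 48)

  # degenerate: every pair equal
  deg <- wilcoxon_pratt(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$z, 0)
  expect_equal(deg$p_two_sided, 1)

  expect_error(wilcoxon_pratt(1:3, 1:2), class = "roostnet_data_error")
  expect_error(wilcoxon_pratt(1, 2), class = "roostnet_data_error")
})

test_that("normal approximation tracks the exact permutation test for small n", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(9:12, 1)
    before <- rnorm(n)
    after <- before - rnorm(n, sd = 1)  # no zeros or ties a.s.
    res <- wilcoxon_pratt(before, after)
    p_exact <- exact_signed_rank_p(before, after)
    expect_lt(abs(res$p_two_sided - p_exact), 0.02)
  }
})

test_that("key-roost selection ranks by measure with a flagged lexicographic tie rule", {
  net <- build_network(table1_fixture(), "Caledonia")
  ct <- centrality_table(net)
  expect_equal(select_key_roosts(ct, 3, "degree"),
               c("Caledonia", "Upper Clements", "Bridgetown"),
               ignore_attr = TRUE)
  clo3 <- select_key_roosts(ct, 3, "closeness")
  expect_setequal(as.vector(clo3),
                  c("Caledonia", "Upper Clements", "Marshalltown"))
  expect_equal(clo3[1], "Caledonia", ignore_attr = TRUE)
  # the Upper Clements / Marshalltown tie (both 1/16) is flagged
  expect_equal(attr(clo3, "ties"), c("Marshalltown", "Upper Clements"))
  # k = node count returns everything, sorted by the measure
  expect_setequal(as.vector(select_key_roosts(ct, 10, "degree")), ct$roost)
  expect_error(select_key_roosts(ct, 0, "degree"),
               class = "roostnet_config_error")
  expect_error(select_key_roosts(ct, 11, "degree"),
               class = "roostnet_config_error")
})

test_that("knockout analysis reproduces the published reduced-network cells", {
  net <- build_network(table1_fixture(), "Caledonia")
  ko <- knockout_analysis(net, c("Bridgetown", "Upper Clements"))

  nb <- ko$removals[["Bridgetown"]]$table
  expect_equal(nb$degree_centrality[nb$roost == "Caledonia"], 8 / 9)
  expect_false("Bridgetown" %in% nb$roost)

  nu <- ko$removals[["Upper Clements"]]$table
  expect_equal(nu$degree_centrality[nu$roost == "Caledonia"], 7 / 8)

  # closeness signed-rank for the Bridgetown knockout: all nine survivors
  # lose closeness, one tied pair of differences -> z = 2.668
  t_clo <- ko$removals[["Bridgetown"]]$tests$closeness
  expect_equal(t_clo$n_pairs, 9)
  expect_equal(t_clo$w_plus, 45)
  expect_equal(t_clo$variance, 71.25 - 6 / 48)
  expect_equal(round_half_up(t_clo$z, 3), 2.668)
  expect_equal(round_half_up(t_clo$p_two_sided, 3), 0.008)

  expect_error(knockout_analysis(net, c("Caledonia", "Caledonia")),
               class = "roostnet_data_error")
  expect_error(knockout_analysis(net, "Foo"), class = "roostnet_data_error")
})

test_that("rounded-input mode tests table-precision values", {
  net <- build_network(table1_fixture(), "Caledonia")
  ko <- knockout_analysis(net, "Marshalltown", values = "rounded")
  t_deg <- ko$removals[["Marshalltown"]]$tests$degree
  # at 3 decimals the unchanged degrees become exact zeros handled by Pratt
  expect_gt(t_deg$n_zero, 0)
})

test_that("knockout reports serialize losslessly to JSON and write CSV", {
  net <- build_network(table1_fixture(), "Caledonia")
  ko <- knockout_analysis(net, c("Bridgetown", "Caledonia"))

  j <- withr::local_tempfile(fileext = ".json")
  write_knockout_json(ko, j)
  back <- read_knockout_json(j)
  expect_equal(back$full, ko$full)
  expect_equal(names(back$removals), names(ko$removals))
  expect_equal(back$removals[["Bridgetown"]]$table,
               ko$removals[["Bridgetown"]]$table)
  expect_equal(back$removals[["Bridgetown"]]$tests$closeness$z,
               ko$removals[["Bridgetown"]]$tests$closeness$z)

  f <- withr::local_tempfile(fileext = ".csv")
  write_knockout_csv(ko, f)
  csv <- utils::read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
  expect_equal(nrow(csv), 12)  # 10 roosts + z + p rows
  expect_true(all(c("all_sites_degree", "no_Bridgetown_closeness") %in%
                    names(csv)))
  expect_true(is.na(csv$no_Bridgetown_degree[csv$roost == "Bridgetown"]))
})
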