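# roostnet

Spatial networks of communal roost sites from automated radio-telemetry.

Communally roosting birds such as chimney swifts (*Chaetura pelagica*)
shelter overnight in a handful of large masonry chimneys scattered over a
region. If individuals switch roosts within a season, the roosts form a
network, and graph centrality gives a per-site, quantitative ranking of
conservation importance — useful precisely where biodiversity-centred
metrics say nothing about a single species' urban habitat features.
`roostnet` is aimed at movement ecologists working with Motus-style
automated telemetry who want to go from a raw detection export to that
ranking, and to a prediction of what losing a key roost would do.

The chain it implements:

1. **Filter detections** — drop short runs (run length ≤ 3, false
   positives), keep only the 18:00–10:00 overnight window, and cut the
   season at 1 September (all configurable).
2. **Map towers to roosts** — each tower represents its nearest known
   roost (several towers may pool onto one); a tower > 25 km from every
   known roost marks an inferred, unknown roost at its own location.
3. **Movement sequences** — per-tag chronological roost streams with
   consecutive repeats pooled.
4. **Network** — each consecutive roost pair in a sequence is one edge of
   an undirected multigraph; a bird's initial departure from the single
   tagging site is dropped to correct capture-site bias.
5. **Centrality** — degree `Degree(v) = n_v / n_j` (incident links with
   multiplicity, as a proportion of the maximum `n_j`) and closeness
   `Closeness(v) = 1 / Σ_{i≠v} d_vi` (reciprocal sum of shortest-path
   step counts on the simple projection; unreachable pairs take a
   sentinel distance equal to the node count).
6. **Knockout** — remove a key roost, recompute centralities, and test
   the survivors' paired before/after values with a Wilcoxon–Pratt
   signed-rank test (zeros ranked then discarded; tie-corrected normal
   approximation without continuity correction).

A seeded simulator (`synthetic_study()`, `simulate_tracks()`,
`emit_detections()`) generates Motus-like detection streams from a known
nightly roost-switching Markov chain, so the whole pipeline is testable
against ground truth; `table1_fixture()` packages the 21 published swift
movement sequences that the golden tests reproduce.

## Worked example

```r
library(roostnet)

seqs <- table1_fixture()                       # 21 tagged swifts
net  <- build_network(seqs, tagging_site = "Caledonia")
net
#> Roost network: 10 roosts, 24 links (multigraph)
#>   tagging site: Caledonia

centrality_table(net)
#>             roost raw_degree degree_centrality distance_sum closeness
#> 1       Blandford          2            0.1818           18    0.0556
#> 2      Bridgetown          8            0.7273           17    0.0588
#> 3       Caledonia         11            1.0000           13    0.0769
#> 4      Jordan Bay          1            0.0909           25    0.0400
#> 5       Liverpool          1            0.0909           24    0.0417
#> 6    Marshalltown          5            0.4545           16    0.0625
#> 7       Middleton          4            0.3636           25    0.0400
#> 8  Upper Clements          9            0.8182           16    0.0625
#> 9        Weymouth          4            0.3636           17    0.0588
#> 10      Wolfville          3            0.2727           17    0.0588

knockout_analysis(net, c("Caledonia", "Bridgetown", "Upper Clements"))
#> Roost knockout report (3 removals, raw values)
#>   - Caledonia: degree z = -2.668 (p = 0.008); closeness z = 1.673 (p = 0.094)
#>   - Bridgetown: degree z = -0.296 (p = 0.767); closeness z = 2.668 (p = 0.008)
#>   - Upper Clements: degree z = -0.534 (p = 0.594); closeness z = 2.677 (p = 0.007)
```

Reading the numbers: Caledonia handles the most movement (raw degree 11,
centrality 1.0) and sits closest to everything (distance sum 13 over the
other 9 roosts, closeness 1/13 ≈ 0.077). Removing it significantly
rearranges degree across the survivors (z = −2.668, p = 0.008; negative
because the normalising maximum shrinks, so surviving degrees rise),
while removing Bridgetown or Upper Clements significantly degrades
closeness (z = 2.668 / 2.677) — each disconnects a peripheral roost.
Usage spread: `summarize_roost_usage(seqs)` gives the distinct-roost
histogram `{1: 5, 2: 5, 3: 9, 4: 2}` tags — 76% of birds used more than
one roost.

`run_pipeline(pipeline_config(...))` performs the whole chain from CSV
inputs and writes sequences, edge list, GraphML, centrality table,
knockout report (CSV + JSON), community partition, a network plot with a
deterministic layout sidecar, and a log. A thin CLI wrapper with
`run`, `filter` and `simulate` subcommands is installed at
`inst/cli/roostnet.R`.

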