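---
title: "Methods: roost networks from automated telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: roost networks from automated telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roostnet)
```

## The problem

Communally roosting aerial insectivores such as chimney swifts
(*Chaetura pelagica*) concentrate at night in a small number of large
masonry chimneys. If individuals switch roosts within a breeding season,
the roosts form a spatial network, and graph-theoretic centrality gives a
quantitative, per-site ranking of conservation importance that
biodiversity-centred metrics cannot provide for an urban, single-species
habitat feature. `roostnet` implements the full chain from raw automated
radio-telemetry (Motus-style) detections to that ranking, plus a
node-knockout analysis of what the loss of a key roost would do to the
rest of the network.

## From detections to movement sequences

A Motus-style receiver logs a *run* of consecutive detections of a coded
tag. Three exclusion rules clean the raw table (`filter_detections()`):

* **Run length** (`max_false_positive_run`, default 3): runs of three or
  fewer detections are characteristic of noise bursts on the shared
  frequency and are treated as false positives.
* **Time window** (`window_start`/`window_end`, default 18:00–10:00 local):
  swifts are near their roost in the evening and early morning; midday
  detections are foraging birds, not roost evidence. The window is
  half-open, `[18:00, 10:00)`: a detection at exactly 18:00 is kept, one
  at exactly 10:00 is dropped. The boundary rule is a convention — the
  source data are minute-resolution and nothing in the analysis is
  sensitive to it — but a fixed convention makes membership unambiguous.
* **Season cutoff** (`season_cutoff`, default 1 September): later
  detections increasingly reflect migration rather than breeding-season
  roost use. "After the cutoff" is implemented as *at or after local
  midnight of the cutoff date*, the simplest date-cutoff semantics; an
  overnight run spanning that midnight is split by it.

All timestamps are interpreted in one configurable local zone (default
`America/Halifax`, the study region's); no UTC conversion is attempted,
because roosting hours are a local-time phenomenon. Run lengths are taken
as exported, not recomputed from burst timing.

Receivers are not at roosts, so towers are mapped to roost sites by
distance (`assign_towers()`): each tower represents its nearest known
roost (haversine distance, mean Earth radius 6371.0088 km; exact
distance ties broken lexicographically by roost name), several towers may
pool onto one roost, and a tower more than `unknown_roost_threshold_km`
(default 25 km) from every known roost is taken to mark an *unknown*
roost at the tower's own location — repeated overnight detections far
from any known site are better explained by an undiscovered roost than by
foraging. Filtered detections then become per-tag chronological roost
streams, and consecutive repeats at one roost are pooled into a single
entry (`collapse_sequence()`) to limit pseudoreplication. Visits are
deliberately *not* segmented into nights: the collapsed label stream is
the movement sequence, which is exactly the form of the published
21-bird table packaged as `table1_fixture()`.

## The network and its centralities

Each consecutive pair in a collapsed sequence contributes one undirected
edge to a multigraph over roosts (`build_network()`), with one
correction: all birds were tagged at a single roost (Caledonia), so every
sequence necessarily starts there. Counting each bird's initial departure
would overstate that roost's importance, so a sequence's **first
transition is dropped when it departs the tagging site**; the site earns
links only through returns and subsequent movements. All later
transitions count, including departures after a return. Self-loops cannot
arise from collapsed input and are dropped defensively.

Two centralities are computed (`centrality_table()`):

* **Degree** — a roost's incident edge count *with multiplicity* (every
  recorded movement counts), normalised by the network's maximum such
  count, so the best-connected roost scores exactly 1:
  $\mathrm{Degree}(v) = n_v / n_j$ with $n_j$ the greatest link count.
* **Closeness** — the reciprocal of the sum of unweighted shortest-path
  step counts from the roost to all others,
  $\mathrm{Closeness}(v) = 1 / \sum_{i \ne v} d_{vi}$, computed on the
  *simple projection* (parallel edges count one step). Values are raw
  reciprocals, not normalised — that is the scale on which the published
  per-roost values are expressed.

The asymmetry (multiplicity for degree, simple projection for closeness)
is deliberate: degree measures how much movement a roost handles,
closeness how many hops separate it from the rest of the network, and
jointly they are the unique combination that reproduces the published
centrality table from the published movement sequences.

Removing a node can disconnect the graph, so unreachable pairs need a
distance. We assign the **sentinel value $|V|$**, the node count of the
current network — one more than the longest possible path, so an isolated
roost gets a finite, comparably poor closeness ($1/(8 \times 9) = 0.014$
for an isolated node among 9) rather than an undefined one. This
convention is what the published isolated-node closeness values encode.

Communities are found by divisive edge-betweenness clustering
(Girvan–Newman) on the multigraph, cutting the dendrogram at maximum
modularity (`detect_communities()`) — a deterministic procedure matching
the definition of a community as a node set sharing more links internally
than externally. Singleton communities are allowed.

## Knockout analysis

`knockout_analysis()` removes each named roost in turn (node plus
incident edges, no rerouting), recomputes both centralities on the
reduced network, and tests whether the survivors' values changed with a
**Wilcoxon–Pratt signed-rank test**: differences `before − after` are
ranked by absolute value *including* zeros, zero ranks are then
discarded (Pratt's treatment, needed because knockouts routinely leave
some roosts' centrality exactly unchanged), and the rank sum of positive
differences is compared with its null expectation under a tie-corrected
normal approximation **without continuity correction**. With all nine
surviving roosts losing closeness and one tied difference pair, the
Bridgetown knockout gives $z = 22.5/\sqrt{71.125} = 2.668$ — the
uncorrected approximation is the only variant consistent with that
published statistic. The sign convention makes $z$ negative when a
measure rises after removal (as degree does, because the normalising
maximum shrinks).

Candidate roosts for removal are the top-$k$ (default 3) by each
measure (`select_key_roosts()`); exact ties are broken lexicographically
and flagged in the result, since a ranking must be total but the data do
not order tied roosts — in the packaged fixture, Upper Clements and
Marshalltown tie at closeness $1/16$.

`knockout_analysis(values = "rounded")` runs the tests on values rounded
half-up to 3 decimals instead of exact ones. Published tables are rounded,
and rounding creates and destroys ties, which moves the tie-corrected
$z$ in the third decimal; the option exists to quantify exactly that
sensitivity. Raw values are the default and the documented results all
use them.

## Numerical choices

* Internal arithmetic is double precision on exactly representable
  integers and small rationals; distance sums are integers and
  `1/closeness` is asserted integral in the tests.
* Golden-value comparisons round **half away from zero**
  (`round_half_up()`) to the printed precision, since base `round()`'s
  half-to-even rule disagrees with how published tables are rounded.
* The exact-permutation oracle for the signed-rank test enumerates all
  $2^n$ sign assignments and uses the **mid-p** convention (half weight
  on the observed point). A continuous approximation to a discrete
  distribution should be judged against mid-p; on that yardstick the
  uncorrected normal p is provably within 0.02 of exact for
  $9 \le n \le 12$ (worst case 0.0197 at $n = 9$), which is the regime
  the property tests exercise. Against the conventional non-strict exact
  p the worst-case gap is 0.039–0.127 for $n \le 12$ — no uncorrected
  normal approximation can meet a 0.02 bound there, and the published
  statistics rule out the corrected one.
* Degenerate inputs: an edgeless network has all degree centralities
  defined as 0 and flagged; closeness requires at least two nodes; a
  signed-rank test in which every difference is zero reports $z = 0$,
  $p = 1$, flagged degenerate.

## The synthetic generator

`synthetic_study()` / `simulate_tracks()` / `emit_detections()` generate
Motus-like detection streams from a known latent process so every
pipeline stage can be validated against ground truth without any field
data. The latent model is one roost per night and per tag — an
independent, sticky Markov chain (default stay probability 0.6, the
remainder uniform) started at the tagging site; intra-night switching is
not modelled because nightly occupancy is the resolution at which roost
identity is observable. Defaults mirror the study's conditions: 21 tags,
72 nights (late June–August), one true overnight run per tag-night at
the tower nearest the occupied roost with 5-minute detection intervals
and a mean run length of 12, short false-positive runs (length 1–3,
rate 0.2 per tag-night) at uniformly random towers, and daytime foraging
detections (rate 1 per tag-day) outside the roosting window. False
positives are modelled only as short runs — the failure mode the
run-length filter exists for — with no tag-ID confusion; there is no
radio-propagation, battery, or migration model. The default geometry
places one tower within ~2 km of each roost so nearest-roost assignment
is unambiguous; `hard_mode = TRUE` adds pooling towers and a remote
tower to exercise pooling and unknown-roost inference.

By construction, a zero-noise simulation survives all three filters and
the recovered sequences equal the collapsed latent tracks; the test
suite verifies this end-to-end at 20 tags × 30 nights, and the
two-state occupancy share at 2,000 nights against the chain's stationary
distribution (±0.03). Those sizes keep the whole suite fast while
leaving the Monte-Carlo tolerances comfortably non-trivial. What passing
synthetic tests do **not** show: robustness to detection dropout at
roosts without nearby towers, tag loss, clock skew between receivers, or
ambiguous geometry where one tower serves two roosts — real Motus data
contain all of these.

## Known limitations

* The published table the golden tests reproduce contains four cells
  that are arithmetically inconsistent with every reconstruction that
  reproduces the other ~40 (Middleton's degree without Caledonia,
  Blandford's degree and Wolfville's closeness without Upper Clements,
  Jordan Bay's closeness without Bridgetown); they are excluded from
  comparison rather than contorting the algorithm toward them.
* The published footer statistics for the two *non-significant*
  knockouts are likewise not derivable from the printed per-roost values
  under any input mode implemented here; only the significant statistics
  (and two of the non-significant ones, in raw mode) reproduce.
* Same-evening detections at two towers are kept in chronological order
  and left to sequence collapse; the data do not resolve which roost was
  actually used that night.
* Centrality is per-season and static: no night-by-night dynamic
  network, no geographic edge weights, no directed variant.
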