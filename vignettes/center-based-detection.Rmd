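---
title: "Center-based community detection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-based community detection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`centerfind` rests on a structural premise about communities in networks:
each community is organised around a *center* — a locally dense node
surrounded by members of lower density — and the centers of different
communities lie far apart from one another. Detection therefore proceeds
in three stages.

**1. Density.** Every node $i$ receives a density score $\eta_i$, either
its degree or its *strong-tie* score (the number of triangles through
$i$). Degree is the default: it is cheaper, and on larger networks it
ranks center candidates at least as well as triangles. The strong-tie
variant rewards cohesive neighbourhoods and can be preferable on small
dense graphs; neither dominates, so the choice is a user-visible
parameter rather than an automatic selection.

**2. Reach distance and centrality.** For each node, $\psi_i$ is the
shortest-path distance to the nearest *denser* node, found by a
breadth-first search truncated at a cap (default 3); nodes with no denser
node within the cap — including the global density maximum — receive the
cap. A center is exactly a node where both $\eta$ and $\psi$ are large: a
local density maximum far from anything denser. The two are combined into
the community centrality

$$\gamma_i \;=\; \frac{\eta_i}{\max_j \eta_j}\cdot\frac{\psi_i}{\mathrm{cap}},$$

so $\gamma \in [0,1]$, the global density maximum scores exactly 1, and
on graphs with clear center structure the sorted $\gamma$ curve collapses
after the first $C$ positions. The $C$ largest-$\gamma$ nodes are the
community centers.

**3. Propagation.** Centers keep their own labels; every other node
adopts, one node per iteration, the label most frequent among its already
labeled neighbours. The iteration order is by decreasing $\gamma$ among
eligible nodes, so well-embedded nodes speak before peripheral ones.

### Density ties are a total order

Integer densities tie constantly — on a graph with maximum degree 5
there may be a dozen nodes sharing the top score. If equal-density nodes
ignored each other, every member of a density plateau would claim the
maximal reach distance simultaneously and several centers could be
elected inside one community. The comparison "denser" is therefore a
strict total order: higher $\eta$, then lower node index. Exactly one
node (the first-indexed global maximum) has no denser node at all; its
plateau twins defer to it whenever it lies within the cap. The index
tie-break is arbitrary but deterministic, and every downstream tie rule
(center ranking, propagation order, vote ties) uses the same convention.

### Choosing the number of communities

Two mechanisms are available, and the default (`select = "auto"`) uses
them in the order the method motivates:

* **Turning point.** When the sorted $\gamma$ curve has an *obvious*
  break — the drop ratio $\gamma_{(k)}/\gamma_{(k+1)}$ reaches at least
  `min_ratio = 2.2` somewhere in the head of the curve — the prefix
  length at the largest drop is taken as $C$. The threshold sits
  deliberately above 2: with the default cap of 3, two nodes of similar
  density on either side of a $\psi$ step from 2 to 1 produce a ratio
  approaching 2 through pure distance quantization, with no community
  structure behind it, so a trustworthy break must clear that artifact
  bound with headroom. On the karate network the break ratio is 2.67 at
  $k = 2$, which is what "obvious" looks like in practice.
* **Modularity scan.** Otherwise the full pipeline is run for each
  candidate $C$ (default range $2\ldots\min(20,\lceil\sqrt n\rceil)$)
  and the partition with the largest Newman–Girvan modularity wins, ties
  to the smallest $C$.

A single community is never elected automatically; `C = 1` must be
requested explicitly.

Neither mechanism is universally right, which is why both exist. The
scan inherits modularity's resolution preferences: on sparse graphs a
subdivision finer than the center structure can have strictly higher
modularity, and the scan will — correctly, by its own criterion — return
it. The turning point reads the center structure directly but needs a
genuinely collapsing curve. The obviousness threshold arbitrates between
them.

### Propagation details

"Adopt the most frequent label among labeled neighbours" needs three
auxiliary rules to be well-defined and robust; all are deterministic
total orders.

* **Informedness.** A candidate's vote counts as sufficiently informed
  when a center sits among its labeled neighbours, or when at least half
  of its neighbours are labeled. Each iteration processes the
  largest-$\gamma$ informed candidate; if none exists, the
  largest-$\gamma$ candidate with at least `min_labeled_neighbors`
  (default 1) labeled neighbours is processed anyway, which guarantees
  progress. Without this rule a node whose only labeled neighbours lie
  across inter-community edges votes on misleading evidence while its
  own community is still unlabeled, and the foreign label can cascade
  through the community interior — the dominant failure mode we observed
  on benchmark graphs. Near a center the evidence is authoritative and
  voting early is exactly right.
* **Vote ties** go to the label whose supporters have the greatest total
  $\gamma$, then to the smaller label id.
* **Order ties** (equal $\gamma$) go to the lower node index.

### Disconnected graphs

Communities never span components, and both the capped search and the
propagation are component-confined, so the pipeline runs unchanged on a
disconnected graph (`on_disconnected = "asis"`); every component is
guaranteed a center (a missed component is seeded with its own
highest-$\gamma$ node, counted in the reported $C$). This matters more
than it may appear: faithfully generated sparse benchmarks *are*
disconnected (below), and a largest-component restriction would throw
away exactly the structure the benchmark plants. The default remains to
refuse disconnected input, so accidental disconnection stays visible;
`"largest"` gives the classical restriction used for real datasets such
as the political-blogs network.

### The rich-club pre-screen

The method's known blind spot is the regime where community centers are
directly interconnected: then $\psi$ is 1–2 for almost every node and
$\gamma$ degenerates into a rescaled density. The fraction of realized
edges among the $k$ highest-degree nodes (rich-club connectivity
$\phi$, with $k \approx \log N$ by default) is a cheap advance
indicator: detection warns when $\phi > 0.5$. The threshold and the
logarithmic club size follow the published practice for this indicator;
the club size for any particular analysis is a judgement call, which is
why `rich_club_k` is exposed.

## The benchmark generator

`lfr_benchmark()` emulates the standard planted-community benchmark
family with power-law degrees and community sizes:

* degrees from a truncated power law with exponent `t1` on
  $[x_{\min}, k_{\max}]$, where $x_{\min}$ is solved numerically so the
  continuous mean matches `avg_degree`, and $k_{\max}$ defaults to
  $n/10$ — the truncation that keeps small benchmarks realizable;
* community sizes from a power law with exponent `t2` in
  $[c_{\min}, c_{\max}]$, redrawn and trimmed until they sum exactly to
  $n$ (`t2 = 0` means uniform sizes);
* each node of degree $k$ devotes `round(mu * k)` stubs to
  inter-community links and the rest to its own community; stubs are
  joined by random matching, and self-loops, parallel edges and
  misplaced inter/intra pairs are repaired by partner swaps (bounded
  passes; irreparable stubs are dropped, and generation aborts if more
  than 10% of stubs would be lost);
* overlapping ground truth (`n_overlap` nodes with `m_overlap`
  memberships) splits a node's internal stubs round-robin across its
  communities; only the ground truth is multi-labeled — the detector
  always returns a crisp partition.

Two consequences of the per-node rounding deserve emphasis, because they
define what the sparse benchmark rows actually look like. At `mu = 0.1`
a node needs degree 5 or more before `round(mu * k)` reaches 1, so in a
benchmark with average degree 3 and maximum degree 5 *no node carries an
external stub*: the realized mixing is (near) zero and the communities
are separate components. This is not a defect of the generator — it is
what the reference benchmark model produces at these parameters, it
matches the zero rich-club connectivity published for that configuration,
and it is why the detection pipeline must handle disconnected input.
Correspondingly, the realized mixing fraction tracks `mu` closely only
once degrees are large enough to resolve it (within ±0.03 at average
degree 20 in our property tests, frozen after a 20-seed calibration);
for the sparse rows it is biased toward zero, deliberately.

What the generator does **not** emulate: correlation between a node's
degree and its community's size (degrees are drawn independently of the
assignment), weighted or directed variants, and the reference
implementation's exact rewiring order (seeded runs are reproducible
against *this* implementation only). The independence of degrees and
communities matters for interpretation: in a draw with unequal community
sizes the largest community usually also contains the highest-degree
nodes, so the top of the $\gamma$ ranking can concentrate there. Passing
recovery tests on these graphs therefore demonstrates recovery under
exactly that adversity, but says nothing about, e.g., degree-corrected
block-model data.

### Evaluation protocol for generated benchmarks

Recovery is scored as the median NMI between the detected partition and
the planted one over 10 seeded draws. When the benchmark parameters fix
the community count by arithmetic — `c_min = c_max` divides $n$, as in
the 50-node row (50/25 = 2) — that count is supplied to the detector:
it is a parameter of the experiment, not something read off the realized
graph, and on graphs whose sparse communities genuinely contain
higher-modularity subdivisions no internal criterion could recover it.
When the count is itself random (the 1000-node row draws sizes in
[100, 500]) the detector's automatic selection is used. The acceptance
script implements exactly this protocol.

## Numerical and degenerate-input choices

* $\psi$ values at exactly the cap are indistinguishable from "no denser
  node found": a denser node at distance exactly 3 and none at all both
  give $\psi = 3$. Documented rather than resolved; the stopping rule is
  the point of the cap.
* An edgeless graph has no density maximum; centrality is an error
  rather than a vector of zeros.
* Modularity requires at least one edge; NMI of two single-cluster
  partitions is 1 (they are identical up to relabeling), and the
  $0/0$ convention elsewhere resolves to 0.
* The modularity scan treats improvements below $10^{-12}$ as ties and
  keeps the smaller $C$.
* Membership files are two whitespace-separated columns; node labels are
  arbitrary strings, internal order is first appearance, and all
  reported results use the original labels.

## Problem sizes in the test suite

The suite exercises the oracle equivalences on 100 random graphs of up
to 50 nodes (reach distance vs all-pairs BFS) and 10–15 graphs of up to
30–40 nodes (modularity, NMI, triangle counts vs explicit enumeration);
benchmark recovery uses 10 draws each of the 50-node and 1000-node rows;
parameter recovery uses 10 draws of 300-node planted partitions for each
block count in 2–4. These sizes were chosen so the whole suite exercises
every code path in well under normal package-check time while keeping
the stochastic medians stable.

## Known limitations

* **Interconnected centers.** When high-degree nodes of different
  communities sit within one or two steps of each other, $\psi$
  saturates and center election degenerates to a degree ranking. On
  equal-size planted partitions with non-trivial `p_out` this shows up
  as order-statistics luck: the top-$C$ nodes land two-in-one-block in a
  substantial fraction of draws, the scan then needs $C+1$ centers to
  cover every block, and the recovered count overshoots by one with a
  small NMI cost. The rich-club pre-screen exists precisely to flag this
  regime; with `p_out = 0` election is provably one-per-block and
  recovery is exact.
* **One-shot greedy voting.** Labels are never revised, so an early
  wrong vote cannot be repaired later; the informedness rule reduces,
  but cannot eliminate, this risk on graphs with weak community
  boundaries.
* **Resolution.** The scan inherits modularity's resolution limit in
  both directions (it can prefer merging small communities or splitting
  sparse ones); the turning point only helps when the centrality curve
  actually collapses.
* **Crisp output.** Overlapping community structure is represented in
  generated ground truth but never in detector output.
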