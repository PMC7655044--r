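---
title: "Activation cascades, path centrality and the hourglass waist"
author: "altcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation cascades, path centrality and the hourglass waist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altcascade)
```

## The model

`altcascade` studies how evoked activity spreads over a directed, weighted,
spatially embedded brain network. Each region of interest (ROI) is a node;
each axonal projection is an edge carrying a connection-density weight
$w_{ji}$, a statistical confidence $p$-value, a Euclidean length between the
ROI centroids, and a communication delay $t_{ji}$ proportional to that
length. The dynamics are the asynchronous linear threshold (ALT) model: a
node is binary (inactive/active), the designated source is active at
$t = 0$, and node $i$ activates at the first instant $t$ at which

$$\sum_{j \in N_{\mathrm{in}}(i)} w_{ji}\, s_j(t - t_{ji}) > \theta,$$

i.e. when the summed weights of inputs that have already arrived from
active in-neighbors strictly exceed the threshold $\theta$. Activation is
monotone — there is no refractoriness, deactivation or re-excitation; the
model deliberately captures only the first feed-forward ripple of evoked
activity. Because candidate activation times are exactly the input arrival
instants, the simulator is an exact continuous-time event queue; no clock
discretization is involved. Input arrivals sharing a timestamp are summed
before the threshold test, and simultaneous activations are processed in
node order (which affects nothing observable, only iteration order).

Every run yields a *causal cascade DAG*: edge $(j \to i)$ is kept exactly
when $j$ is an in-neighbor of $i$, both activated, and
$t_i^a \ge t_j^a + t_{ji}$ — $j$'s input had arrived by the time $i$
fired, so $j$ contributed causally, even if its individual weight was
below threshold. Delays are strictly positive, so these edges always point
forward in time and the result is acyclic by construction.

## Analyzing collections of cascades

A *source-target path* runs from the cascade's source to a terminal (a
node without outgoing causal edges) and must contain at least one edge.
Path counts are computed by dynamic programming in topological order
(counts $f$ from the source, $g$ to the terminals), exactly, in doubles:
exact up to $2^{53}$, with an explicit overflow error beyond that —
network sizes in scope stay many orders of magnitude below the limit.

*Path centrality* $P(v)$ is the fraction of all source-target paths,
pooled over the cascade collection (one cascade per sensory source), that
traverse $v$. The *$\tau$-core* is a greedily approximated minimal node
set jointly covering at least a fraction $\tau$ of those paths (the exact
problem is NP-hard): each iteration picks the node lying on the most
not-yet-covered paths, deletes it from every DAG, and recounts. When the
$\tau$-core is small relative to the network, the architecture is an
*hourglass*: many sensory streams squeeze through a narrow integrative
waist before fanning out again.

Two deliberate choices in the greedy:

* After deleting core members, remaining paths are counted from the
  source to the **original** terminals only. Deleting a node can expose
  new dead-ends; counting paths into those would silently change the path
  universe, making "coverage" inexact. With fixed terminals the covered
  fraction over the original path set is exact. (The alternative reading
  of "remove the node from all cascades" is ambiguous on this point.)
* Ties are broken toward the node earliest in the collection's node
  order, making the trajectory fully deterministic. Sources are eligible
  core candidates by default (in practice they are rarely selected, since
  each source only covers its own cascade's paths).

Cascade similarity is the Jaccard index on causal edge sets;
`cascade_dendrogram()` feeds `1 - Jaccard` to average/single/complete
agglomerative clustering (`stats::hclust`) and serializes to Newick via
`ape`. Location metrics are the hop distance from the source within the
DAG (`source_distance`) and the count of DAG-reachable nodes
(`influence`). When subcortical nodes are present, `classify_paths()`
partitions paths into C (all cortical), CS (one cortico-subcortical
boundary crossing, subcortical terminus), CSC+ (two or more crossings,
cortical terminus), and an explicitly reported residual class, by dynamic
programming over (node, capped crossing count) states.

## Parameters that matter

* **`theta`** (dimensionless, > 0): the only dynamical parameter.
  `find_critical_theta()` selects the largest grid value at which every
  source yields a complete cascade — the working regime, chosen because
  imaging shows at least some evoked activity in all cortical regions
  after any sensory stimulation, while larger values abolish the cascade.
* **`weight_mode`**: `"raw"` (default) applies $\theta$ to weights as
  given, matching the threshold inequality above. `"in_normalized"`
  rescales each node's in-weights to sum to one, so $\theta$ reads as a
  *fraction of afferent drive* — the scale on which a single threshold
  has the same meaning at every node regardless of its in-strength. The
  sharp-transition analysis below uses this mode for exactly that reason.
* **`conduction_factor`** (time units per mm, default 1): delays are
  lengths times this factor. No conduction velocity is asserted; all
  relative orderings — everything the package compares against data —
  are invariant to it.
* **`alpha`** (default 0.05): edges with $p \le \alpha$ are retained (the
  boundary value is kept; whether exact equality was kept upstream is
  unknowable from a "filter out $p$ higher than 0.05" rule, and keeping
  it is the conservative reading). Sensible range 0.01–0.1.
* **`tau`** (default 0.9): target path coverage of the core.

## Null models

Four seeded randomizations probe which ingredients of the connectome
produce the hourglass: permute weights, permute lengths (delays refresh),
permute both independently (destroying any weight-length correlation),
and degree-preserving topology rewiring by double-edge swaps (10 accepted
swaps per edge by default; swaps creating self-loops or duplicates are
rejected). In topology rewiring, weights travel with their edges while
lengths are recomputed from the new endpoint centroids — the physically
consistent choice, since length is a property of the embedded node pair,
not of the connection label; `carry_lengths = TRUE` gives the
alternative. `ensemble_tau_core()` repeats the whole
randomize → simulate → core pipeline per replicate and reports 5/50/95
percentile core-size bands and per-node core-membership frequencies.

## Comparison with VSD imaging

Voltage-sensitive-dye recordings give a frame-quantized view of cortical
activation (nominally 6.67 ms/frame). The pipeline is: least-squares
affine landmark registration (`fit_affine_landmarks`), per-pixel
activation time as the earliest poststimulus intensity argmax
(`pixel_activation_time`), per-ROI activation frame as the modal pixel
frame with ties to the earliest frame (`roi_activation_time`), and
pairwise order comparison (`temporal_agreement`): for every ROI pair
ranked by the model, same experimental frame counts as insufficient
resolution, same order as agreement, opposite as disagreement; the three
fractions sum to one exactly. Pairs the model itself cannot rank
(numerically equal times, possible with symmetric delays) are excluded
from the denominator. Kendall's $\tau$-b accompanies the fractions
because experimental frames are heavily tied; it — like the whole
comparison — is invariant to any strictly monotone transform of model
times, so the arbitrary model time unit is irrelevant.
`shuffled_baseline()` scrambles ROI-frame assignments while preserving
the per-frame activation counts, giving the chance level against which
agreement is judged.

## What the synthetic generators emulate — and what they do not

`generate_connectome()` reproduces the summary signature of the
right-hemisphere mouse cortical network: 67 nodes, density 13.9%,
directed (Fagiolo total) clustering near 0.60, log-normal weights
anchored at an 80th percentile of 5 and a maximum near 40, ten flagged
sensory sources, and a $p$-value mixture (90% below 0.05) so the
confidence filter is exercised. Nodes are placed uniformly in a thin
sheet-like box (17 × 17 × 0.85 mm — the cortex is a quasi-2D surface),
and directed edges are drawn with probability
$p(d) = \exp(-(d/\lambda)^6)$ in centroid distance $d$; $\lambda$ is
calibrated by bisection on the *expected* density given the sampled
positions, and 60% of drawn edges are reciprocated, mirroring the high
reciprocity of cortical connectivity. Clustering then emerges from the
spatial embedding rather than from explicit triangle closure. Because
the published statistics describe the confidence-filtered network — and
a finite directed diameter presumes every region reachable — draws are
conditioned on strong connectivity of the $p \le 0.05$ subgraph
(rejection sampling with seeds derived deterministically from the spec
seed).

Known limitations, hence what passing tests do *not* show about real
data: realized edge lengths concentrate in roughly 0.3–5 mm rather than
the near-uniform 1–7 mm of the real network — under a pure
distance-decay model, clustering of 0.6 at this size and density forces
strong locality, and adding long-range edges demonstrably destroys the
clustering target, so the generator matches the clustering/density pair
and only approximates the length marginal. Weights are i.i.d., not
coupled to distance or reciprocity; out-degree variance is not inflated
to the real network's $\sigma \approx 8.3$; and no attempt is made to
reproduce actual ROI geometry, acronyms, or hemispheric asymmetries.

One consequence of i.i.d. weights deserves emphasis: with raw weights the
decline of cascade size in $\theta$ shows intermediate plateaus (nodes
with atypically weak in-edges drop out one by one), so the collapse from
complete cascade to source-only is gradual on the raw-$\theta$ axis. On
the normalized (fraction-of-drive) axis the typical source shows a sharp
jump — the form in which the package tests the transition. In the real
network, strong short-range connections are mutually correlated with the
topology, which is expected to sharpen the raw-weight transition in a way
an i.i.d. weight model cannot.

`generate_hourglass()` plants ground truth: sources project only to a
small waist, the waist to all downstream nodes, with an optional leakage
fraction of direct source-downstream edges. At zero leakage the waist
covers every source-target path, so the greedy core must recover exactly
the waist — the package's strongest end-to-end correctness check.
`generate_vsd_stack()` quantizes planted ROI times to 0-based frames
(`floor(t / 6.67 ms)`, stimulus at frame 0) and gives each pixel a
unit-amplitude Gaussian temporal bump (width 1.5 frames) plus i.i.d.
Gaussian noise; at zero noise the extraction pipeline recovers the
planted frames exactly, and recovery degrades with the noise level.

## Numerical choices and degenerate inputs

Event times are sums of floating-point delays, so simultaneity uses an
absolute-plus-relative tolerance of $10^{-9}(1 + |t|)$, both when pooling
same-instant arrivals and when applying the causal-DAG inequality.
Ties in the per-pixel argmax and in the per-ROI mode resolve to the
earliest frame. Cascades that activate only their source contribute zero
paths; collections whose every cascade is degenerate are an error, as are
empty edge sets in the Jaccard index, coincident centroids on a connected
node pair (a zero delay is ill-posed), unclassified nodes in the path
classification, and landmark configurations that are collinear/coplanar.
A 2-cycle admits no valid double-edge swap; the rewiring then returns its
input flagged `no_valid_swap` with a warning rather than looping forever.

## Problem sizes in the shipped tests

The test suite checks the event-driven simulator against brute-force
time stepping on 200 random networks of up to 12 nodes with integer
delays, path-count DP against exhaustive DFS enumeration on 200 random
DAGs, and the greedy core against an explicit enumerated-path-set greedy
on 100 random collections — sizes at which exhaustive oracles are exact
and fast. End-to-end checks run the full 67-node synthetic pipeline:
waist recovery on the planted hourglass with 20 topology-null
replicates, a 20-seed VSD round trip at noise SD 0.1 on 72 × 72 stacks,
100-replicate conservation checks for all four null models, and the
sharp-transition measurement via bisection on the threshold axis. The
same scales are used by `scripts/acceptance.R`, which reruns the whole
analysis from scratch and emits its principal quantities as JSON.
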