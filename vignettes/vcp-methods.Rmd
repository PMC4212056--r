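---
title: "Vertex collocation profiles: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex collocation profiles: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcprofiles)
```

## The model

A vertex collocation profile describes a vertex pair (v_s, v_t) by a census
of its joint embeddings: for every selection of n − 2 *free* vertices from
V \ {v_s, v_t}, the induced n-vertex subgraph over r relation types (and
optionally edge directions) falls into exactly one isomorphism class among
those that keep v_s and v_t fixed, and the profile counts how many
selections land in each class. Conservation is therefore structural, not
statistical: the counts of a 3-vertex profile always sum to |V| − 2, and a
4-vertex profile to (|V| − 2)(|V| − 3)/2. The assumptions are minimal —
simple graphs without self-loops, relations reducible to per-edge bitmasks,
and a pair-centric notion of locality. Edge weights are outside the model;
anything categorical (or quantizable) can ride along as a relation bit.

Two labeled vertices is the deliberate choice that separates VCP elements
from plain isomorphism classes: mappings that exchange v_s and v_t are *not*
collapsed, so a profile retains the asymmetry between the source's and the
target's local topology. With one free vertex (n = 3) nothing collapses at
all and every subgraph address is its own element; with n = 4 the two free
vertices generate a 2-element permutation group and the universe of 2^{2r}
(undirected) or 2^{4r} (directed)-valued cell assignments folds accordingly.

## Addressing conventions

Every subgraph on labels 1..n is addressed by packing one cell per
unordered label pair into an integer. The conventions, fixed throughout the
package and its file formats (`layout=1` in headers):

* cell order (1,2), (1,3), …, (n−1,n); significance *increases* along that
  order, so the (1,2) cell holds the least significant bits;
* a directed cell holds the forward block (edge from lower to higher label)
  in its low r bits, then the backward block;
* the canonical representative of an isomorphism class is the **minimum**
  address over all (n−2)! free-vertex permutations;
* static element indices are 0-based and contiguous in increasing
  canonical-address order.

These four choices are mutually constraining and are pinned by worked
examples in the test suite: the directed 4-vertex universe has 2112
elements against 2176 for its undirected 2-relation pseudo-equivalent, the
addresses 1364 and 2388 collapse to element 884 in the former and map to
792 and 1336 in the latter, and exactly 20 of the 40 elements of
VCP^{4,1,0} contain the free–free edge. An alternative "s–t cell most
significant" layout (`shift_st`) is available for link-prediction use,
where the pair under scrutiny has no edge and the populated part of the
vector then clusters in the low half of the address space; all printed
examples and all defaults use the standard layout.

Addresses are held in doubles and are exact up to 52 address bits, which
covers every universe the profile counters accept. Beyond that (large n·r
in dynamic mode) the package works on per-pair cell vectors with string
memo keys, and canonical selection compares cells from the most significant
pair downward — the same ordering the minimum address induces. This keeps
the package free of big-integer dependencies at no loss of exactness.

## Static and dynamic mappings

The static mapping enumerates the universe once and canonicalizes every
address in a vectorized sweep. A free-vertex permutation moves whole cells
and, in directed universes, swaps forward/backward blocks of the cell whose
endpoints change order — in other words it is a pure *bit permutation* of
the address. The sweep exploits this by building two half-word lookup
tables per permutation and taking a running elementwise minimum over the
whole address vector; the largest bundled case (n = 7, 2^21 addresses, 120
permutations) completes in seconds. The enumeration cap defaults to 2^24
addresses; beyond it the constructor refuses and points to dynamic mode,
which canonicalizes a subgraph on first observation, memoizes its whole
orbit, and uses the canonical address itself as the (non-contiguous)
element id.

Cardinalities have an independent check that never enumerates: by the
orbit-counting lemma the number of classes is the group average of
fixed-point counts, and an address is fixed by a permutation exactly when
its r-bit blocks are constant on the cycles of the induced block
permutation, giving (2^r)^cycles fixed points per permutation. Enumeration
and the cycle-structure count agree on every bundled universe — including
1992 elements for n = 6 and 24416 for n = 7, r = 1, undirected.

## Profile counting

The naive counters (`vcp3_naive`, `vcp4_naive`) enumerate every free-vertex
selection against a dense mask matrix; they are the oracles the optimized
counters are tested against, exact to the sparse map. The optimized n = 3
counter merges the two sorted adjacency lists in one pass and obtains the
fully detached element arithmetically. The optimized n = 4 counter loops
over the pair's neighborhood N = Γ(s) ∪ Γ(t):

1. free pairs inside N are counted directly, with the free–free mask read
   from the current neighbor's adjacency;
2. two-hop structures pair a neighbor k with Γ(k) \ (N ∪ {s,t});
3. each k also contributes |V \ (N ∪ Γ(k) ∪ {s,t})| structures whose fourth
   vertex is isolated — a closed form, never a scan;
4. detached connected free pairs come from a per-graph table of edge
   relation-combination frequencies, decremented for every edge met with an
   endpoint in {s,t} ∪ N; what remains are exactly the edges lying wholly
   outside the pair's neighborhood;
5. detached unconnected free pairs are the remaining gap count.

Steps 1–2 and 4 touch only adjacency lists of the pair and its neighbors,
so per-pair work scales with neighborhood sizes and not with |V| (asserted
in the tests by comparing touched-operation counts at |V| = 1000 vs 4000
under equal mean degree). For r above 16 the combination table is not
maintained and detached elements are omitted with a notice — they carry
little discriminative information relative to their bookkeeping cost, and
`omit_detached` exposes the same trade-off at any r.

Free-vertex pairs are enumerated unordered. Enumerating ordered pairs and
halving was rejected: orbits fixed under the free-vertex swap would be
halved incorrectly, breaking exact conservation.

## Temporal encoding

Longitudinal streams become multirelational graphs by dividing time into
chunks, grouping chunks into snapshots, and recording the snapshot of an
event as its relation. Relation 1 is the *oldest* snapshot, so recency
occupies the high bits of each cell; the choice is a convention (the
methods work identically with the reverse) fixed here so that profiles of
temporally active pairs sort into high addresses. Snapshots are half-open
intervals, which makes contiguity unambiguous. The equal scheme splits
chunks as evenly as possible with the *oldest* snapshot absorbing the
remainder; the exponential scheme gives the newest snapshot two chunks —
two rather than one to buffer short-period periodicity — doubling per older
snapshot, oldest again absorbing the deficit. Both follow from treating the
oldest data as least informative, a premise the split-point behavior of the
supervised experiments supports.

The reordering control (`reorder_events`) permutes the assignment of
timestamps to vertex pairs. Both multisets are preserved, hence so is every
union graph over a covering window — only snapshot membership changes. Any
performance that survives reordering is attributable to edge multiplicity
(weight surrogacy), not temporal structure.

## Synthetic generators

The adversarial Erdős–Rényi model draws a candidate edge per pair with
probability `p_edge` and then each of r relations with probability `p_rel`
(a candidate can end up with no relations — candidacy does not imply a
link). It is the stress case for element population: moderate density and
moderate relation probability maximize isomorphism-class diversity, and the
tests assert the interior-maximum shape plus a sub-50% population bound for
the 3-relation universe at sub-30% candidate density on 100 vertices.

The longitudinal generator is package test machinery, not a reconstruction
of any published data set. Each event either closes a wedge or joins a
uniform random pair (`p_close = 0.8` of events attempt closure). Closure
samples an earlier event with weight exp(−recency_bias · (age − lag)) once
the edge is older than the formation latency `lag`, then a second eligible
event incident to one of its endpoints, and links the outer endpoints. The
latency (default 1 chunk) is what makes the signal *learnable*: link
formation follows earlier interaction with a delay, so closures occurring
in a label window cite wedges that are visible in the feature window.
Defaults — 100 vertices, 6 chunks × 120 events, bias 3, lag 1 — produce
union graphs of mean degree ≈ 8 and candidate sets of 1.5–2 thousand
ℓ=2 pairs, sizes chosen as typical of sparse social-interaction networks
while keeping the full 10-seed benchmark suite in the minutes range.
What passing tests on this generator do **not** show: robustness to
degree heterogeneity and community structure of real networks, to
non-stationary event rates, or to periodicity; the generator has none of
these features.

## The supervised pipeline

Candidates are unordered pairs at geodesic distance exactly two (directed
graphs are projected to their undirected union for candidacy only — the
features keep full directional masks). Labels come from a strictly later
window; any window overlap is a hard error rather than a warning, since
leakage silently inflates every metric downstream. Training sets are
undersampled to 25% positive prevalence (all positives kept; negatives
uniformly subsampled); test sets are never touched. The classifier is a
bagged random-subspace ensemble, 10 bootstrap bags × 10 trees each on a
random half of the features, with classification trees delegated to rpart;
the ensemble is configuration, not contribution — any probabilistic
classifier slots in, and no package test depends on classifier internals
beyond the sanity controls. Scores for undirected targets can be
symmetrized by the arithmetic mean of the two pair orientations.

Feature ranking uses information gain over the exact count values of each
element, computed from single-pass ordered value-frequency maps (a
non-contiguous counting sort, with absent elements contributing value 0);
ties break by element id for determinism. Evaluation implements AUROC by
midrank (Mann–Whitney) and AUPR as the step-function area of the
precision–recall curve with tied scores entering as one block and no
interpolation — under that convention a constant scorer yields AUROC 0.5
and AUPR equal to prevalence. Both are verified against an exhaustive
threshold-sweep oracle to 1e−9 and AUROC additionally against an external
reference implementation.

Where two pipelines are compared across seeds, significance is assessed
with a paired sign test (exact binomial on wins among non-ties); the test
statement in the sources names the test because conventions differ.

## Numerical and degenerate-input choices

* Chunk boundaries place the final boundary just above the last event so
  half-open intervals cover the stream; by-count chunking never splits tied
  timestamps and errors when k exceeds the number of distinct times.
* Empty graphs require an explicit vertex count (there is nothing to infer
  from), and profile conservation holds down to |V| = n.
* Evaluation refuses single-class inputs; balancing refuses datasets with
  no positives; the classifier refuses single-class training sets.
* Null (permuted-label) performance is asserted on the mean of many
  replicates: a null-trained ensemble emits few distinct score values, so
  single-replicate AUROC is heavy-tailed by construction, and per-replicate
  bounds would either be vacuous or flaky.
* Benchmark problem sizes (10 seeds × 100 vertices, ~1800 candidates per
  side) are the package's chosen study conditions; the oracle-equivalence
  suite uses graphs up to 30 vertices because the naive oracles are
  quadratic in |V| per pair.

## Known limitations

Optimized counters exist for n = 3 and n = 4 only; larger n falls back to
naive-style enumeration, exponential in n by nature. Profile counting
requires the universe to fit 52 address bits ((d+1)·r·n(n−1)/2 ≤ 52);
dynamic element identification alone has no such bound. Edge weights are
ignored by design. Parallelism is left to the caller by sharding pair
lists — per-pair computations are fully independent.
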