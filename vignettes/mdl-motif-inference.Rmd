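---
title: "Compression-based motif-set inference: models, codes and design choices"
author: "mdlmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-based motif-set inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlmotif)
```

# The inference problem

Classic network-motif analysis counts each small subgraph class (*graphlet*)
in an observed directed graph and compares the count with its distribution
under a user-chosen null model; over-represented graphlets are declared
motifs. That procedure cannot compare the significance of different motifs,
struggles with the multiplicity of ~10,000 five-node graphlet classes and
with correlations between their counts, and its outcome depends strongly on
the null model chosen beforehand.

`mdlmotif` treats motif mining as model selection by lossless compression.
A candidate motif set is good exactly when describing the graph *through*
it — replacing each motif occurrence by a single supernode and encoding the
reduced multigraph plus the information to undo the replacement — takes
fewer bits than describing the graph directly. The minimum description
length (MDL) principle then selects, among all candidate descriptions, the
one with the shortest total codelength. Because purely dyadic descriptions
(edge counts, degree sequences, reciprocity) compete in the same currency,
the method never needs a pre-specified null model and automatically accounts
for multiple testing: every extra motif must pay for its own description
before it can help.

# The description and its four-part codelength

A state of the model is a reduced multigraph `H` obtained from the observed
simple digraph `G` by contracting node-disjoint induced subgraphs, each
classified as a graphlet from a dictionary (by default all weakly connected
3–5-node classes; the enumeration yields 13 + 199 + 9364 = 9576 of them).
The total codelength decomposes as

* **motif set** — identities of the distinct motifs (`log2 |Gamma|` bits
  each), their repetition counts, and the two scalars `|Gamma|` and
  `m_max`, each with the universal integer code `L_N(n) = log2[n(n+1)]`;
* **reduced multigraph** — a microcanonical two-part code: the entropy of a
  maximum-entropy ensemble constrained on the chosen features plus the
  parametric cost of those features;
* **supernode labels** — which nodes of `H` are supernodes and which
  graphlet each carries;
* **reconstruction** — the original node labeling, one orientation per
  contracted subgraph (`log2 n!/|Aut|` bits), and the *rewiring cost*: for
  each supernode, the binomial choice of which internal nodes its incident
  multiedges attach to.

Four base families encode `H`: Erdős–Rényi (ER, fixing node and edge
counts), the directed configuration model (CM, fixing all in- and
out-degrees), and their reciprocal refinements (RER and RCM) that
additionally fix the reciprocated/non-reciprocated split, either globally
or per node. The motif-free *simple-graph* versions of all four codes enter
model selection as references, so on a structureless graph the selected
model is a dyadic one and the motif set stays empty.

## Conventions fixed by oracles

Several printed forms of these codes are ambiguous in sign and fraction
placement. The package fixes them operationally:

* the CM and RCM multigraph codes are *stub-matching* codes; the product of
  multiedge factorials appears as a divisor of the graph's probability.
  A test sums `2^-S` over brute-force-enumerable ensembles: the multigraph
  ER code and the simple ER and RER codes sum to exactly 1, all others to
  at most 1;
* zero-capable integers (the reciprocity split `E_m`, `E_d`, a sequence
  minimum, the edge count of a fully contracted multigraph) are encoded
  through the guarded `L_N(max(n, 1))`. The deviation from any alternative
  convention is a few bits and is dwarfed by the codelength differences the
  method acts on;
* the degree-sequence code takes the minimum of a uniform code over the
  value range and two prequential Dirichlet–multinomial codes
  (concentration 1 and 1/2), plus `log2 3` bits for the choice and the
  integer code of the length. As the concentration grows the
  Dirichlet–multinomial code approaches the uniform one (a tested sanity
  property).

A caveat worth stating: the reciprocal codes encode the reciprocated and
single-edge streams separately and therefore pay an implicit interleaving
penalty; as a consequence `S_RER <= S_ER` does *not* hold pointwise for
these exact codes even though the RER *ensemble* is strictly smaller. The
relations that do hold in the regime the optimizer visits
(`S_RCM <= S_CM`, `S_RCM <= S_RER`, `S_CM <= S_ER` on multigraph views of
simple graphs and contracted states) are property-tested; model selection
is unaffected because families compete through their total codelengths.

# The search

The codelength landscape over motif sets is combinatorial, so the package
uses a stochastic greedy search. After an exhaustive ESU census stores
every occurrence of every dictionary graphlet, each iteration samples up to
`B` surviving occurrences per graphlet (default `B = 25`; results are
stable for 10–100), discards draws overlapping existing supernodes,
evaluates the codelength gain of each candidate contraction, and contracts
the best one — even when the best gain is negative, since later
contractions may recoup the cost. The run ends when no occurrence free of
supernodes remains, and the state with the minimum codelength along the
trajectory is returned. One sampling detail matters for faithfulness:
unselected batch members return to the surviving pool. Discarding them
permanently would cap the inferred multiplicity of any motif with few
occurrences near one and would end runs before the stated stopping
condition (no supernode-free occurrence left) is reached.

Gains are computed incrementally from running sufficient statistics in
compiled code; the R layer implements the same codelengths by naive full
recomputation, and the suite validates hundreds of candidate gains and
whole trajectories against it to `1e-6` bits. Ties in the batch argmax are
broken by gain, then dictionary order, then lexicographic node subset, so
one `(graph, base, B, seed)` tuple yields one bit-identical trajectory.

Model selection runs the search `nRuns` times per base family (100 runs
suit a production connectome analysis; 5–10 a desk-scale one), takes the
per-family best,
adds the four motif-free references, and reports the overall argmin with
two summaries: `deltaLstar`, the compression relative to the simple ER
code (the graph's absolute compressibility, with the no-hypercompression
bound `p <= 2^-deltaLstar`), and `deltaLmotifs`, the bits gained by the
best motif-based code over the best dyadic one, reported only when a motif
model wins.

# Synthetic data: what it emulates and what it does not

Two generators drive validation.

**Null models.** `randomizeGraph()` resamples a graph under each family's
microcanonical constraint: uniform resampling for ER and RER, double-edge
swap chains for CM and RCM (undirected swaps within the reciprocated
subgraph, directed swaps within the rest, rejecting moves that merge the
two). The chains are run lazily — each step proposes a swap only with
probability 1/2 — because plain double-edge swap chains can be periodic on
small ensembles (a directed 4-cycle alternates between its
Hamiltonian-cycle and dyad-pair classes at every accepted move, so a fixed
even move count can never end in the other class); the lazy half-step
restores aperiodicity. The default budget of about 10 proposed swaps per
edge is common practice; the chains are validated for exact feature
preservation and, on tiny brute-force-enumerable ensembles, for uniform
visiting frequencies. Exact-uniform samplers for the constrained families
are out of scope.

**Planted motifs.** `plantMotifs()` inverts the compression scheme:
designate supernodes in a latent graph, throw `E_latent` multiedges
uniformly over ordered pairs *conditioned on the code's support* (a throw
exceeding a pair's wiring capacity is redrawn — whole-draw rejection is
astronomically unlikely to succeed at realistic densities), then expand
each supernode under a uniformly random orientation with uniformly chosen
binomial wirings. Node and edge counts of the output are exactly
predictable, and contracting the ground-truth subsets restores the latent
multigraph's codelength bit-for-bit (a tested identity).

The benchmark defaults mirror the validation conditions of the method's
source analysis: planted networks with `N = 300` nodes and density 0.025,
twenty planted 5-cliques, five independent graphs per condition; null
networks with features matched to a microcircuit-scale reference of
`N = 198` nodes and `E = 6499` edges. Because the real reference wiring
is not bundled, `connectomeLikeGraph()` provides a synthetic stand-in with
log-normal connection propensities (sdlog 0.8) and 30% of edges in
reciprocated pairs — the degree heterogeneity and reciprocity levels are
the two features of real connectomes the null benchmarks need; it makes no
claim to reproduce any real circuit's higher-order structure. Passing
these tests therefore demonstrates correct inference on graphs whose
dyadic structure resembles real data, not recovery of any published
motif table.

# Numerical choices and scales

* All logarithms are base 2; log-factorials go through `lgamma`; tests use
  a tolerance of `1e-6` bits. Exact codes are nonnegative; the
  asymptotically corrected simple CM/RCM entropies may be slightly negative
  on tiny degenerate graphs and are not asserted nonnegative.
* The census is exhaustive (no stochastic subsampling) and held in memory
  with a configurable occurrence budget; canonical forms are brute-force
  minimum adjacency masks over all node permutations, memoized per induced
  adjacency pattern — correctness over speed, with at most `5! = 120`
  permutations per class.
* The test suite runs the null-stringency benchmark with one greedy run per
  family over five graphs per family at sizes 3–4, and the planted
  benchmark at sizes 3–4 plus the 5-clique with five seeds per condition —
  sizes chosen so the full suite completes on a laptop-class single core
  while exercising the same code paths as a full 3–5 analysis.
* Hypothesis-testing baseline: Gaussian raw p-values by default (empirical
  p-values are available but cannot reach Bonferroni-scale significance at
  desk-scale replicate counts), one-sided for over-representation, flagged
  at `p_raw * |Gamma| < 0.01`.

# Known limitations

* Contractions never overlap and never nest; overlapping supernodes would
  correspond to nested circuit motifs, a different inference problem.
* The greedy optimizer returns a point estimate; it does not quantify the
  posterior variability of the motif set.
* Graphlets are limited to five nodes (the census and the brute-force
  canonical forms both scale steeply beyond that), and graphs with
  self-loops are rejected at parse time (optionally dropped).
* The stub-matching CM/RCM codes are slightly sub-normalized (self-loop
  patterns carry probability mass outside the loop-free ensemble), which
  leaves a few bits on the table but preserves valid, comparable
  codelengths.
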