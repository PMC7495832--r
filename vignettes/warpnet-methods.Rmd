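---
title: "Aligning dynamic networks by time warping: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning dynamic networks by time warping: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpnet)
```

## The problem and the model

`warpnet` solves pairwise global alignment of two *dynamic* networks:
time-ordered sequences of undirected simple-graph snapshots over a shared
node universe, the natural model for protein–protein-interaction (PPI)
data in which many interactions are transient. The output is a one-to-one
node mapping and its score.

The method rests on three components.

**Per-snapshot node features.** Every node present in a snapshot (we take
"present" to mean *incident to at least one edge* — the only observable
signal in an edge-list format) receives the 5-tuple (γ, σ, τ, η, θ):
reputation (dominant-eigenvector entry of the snapshot adjacency matrix),
degree, neighbor-reputation sum, two-hop neighbor count, and the
path-weighted two-hop reputation sum
θ = ½ Σ_{x∈N²_v} k_x · p_xv (p_xv = number of length-2 paths between x
and v; for a node at distance exactly 2 these are precisely the shortest
paths, so p_xv = |N(x) ∩ N(v)|). The tuple mixes scales: γ, τ, θ live on
the unit-eigenvector scale while σ and η are raw counts. We deliberately
do **not** standardize the elements — the squared-difference warping cost
below uses the tuple exactly as defined — so degree-like components
dominate the cost on dense graphs. This is a property of the method as
specified, not an accident, and the tests characterize it as such.

**Time warping.** A node present in m snapshots yields a feature sequence
of length m; cross-network sequences generally differ in length, which
rules out a fixed-index (Euclidean) comparison. Dynamic time warping with
local cost d_ij = Σ_k (p_ik − q_jk)² (squared Euclidean, no square root)
and the standard one-step recurrence produces the cumulative distance
λ(m, n), turned into a similarity s_t = exp(−½ λ²) ∈ (0, 1].

**Search.** Each admissible cross-network pair scores
α·s_h + (1−α)·s_t, where s_h is the min-max-normalized homology score
over the e-value-filtered candidate set Ω (e-value < 1e-7), and the
alignment maximizing the summed pair scores is searched by simulated
annealing from a greedy seed.

## Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `alpha` | 0.5 | weight on sequence vs topological similarity; both information sources are a priori equally credible, and with no homology table α only rescales scores (dimensionless) |
| `evalue_max` | 1e-7 | candidate filter on BLAST e-values (strict `<`), the conventional homology-screen threshold |
| `evalue_floor` | 1e-180 | substitute for e-values reported as exactly 0 before taking −log10 |
| `dtw_normalize` | `FALSE` | divide λ by warping-path length before the Gaussian; off because the plain distance is the method as defined (see Limitations) |
| `t0`, `cooling`, `iters_per_temp`, `min_temp` | 1.0, 0.95, 200·max(\|V1\|,\|V2\|), 1e-4 | geometric annealing schedule; sized so that 6-node instances reach the enumerable optimum in ≥95% of seeded runs while a 100×100 alignment stays below a second |
| `p`, `q` (generator) | 0.3/0.7 and 0.7/0.6 | duplicate-link and divergence probabilities of the two benchmark regimes |
| `n_final`, snapshots | 100 nodes, 5 | benchmark problem size; chosen as a desk-scale instance on which the full 190-alignment experiment completes in about two minutes |

## Numerical choices

- **Eigenvector ("reputation").** The adjacency matrix is symmetric and
  non-negative, so the dominant eigenvector can be oriented entrywise
  non-negative (Perron–Frobenius); we normalize to unit L2 norm — the
  standard reading of "normalized eigenvector", and the one under which
  τ ≤ σ is a checkable bound. Snapshots with ≤ 500 nodes (everything in
  the package's intended range) use `eigen(symmetric = TRUE)`; larger
  ones use power iteration with tolerance 1e-10, at most 10,000
  iterations, started from the all-ones vector, and applied to **A + I**:
  the spectral shift leaves the eigenvector unchanged but guarantees
  convergence on bipartite snapshots, where plain power iteration
  oscillates (|λ_min| = λ_max). On disconnected snapshots one global
  eigenvector is used; nodes outside the dominant component may get
  reputation 0. We explicitly rejected per-component normalization to
  keep a single scale per snapshot.
- **DTW boundaries and ties.** λ(0,0) = 0 and λ(0,·) = λ(·,0) = ∞;
  backtracking compares the three predecessors directly (never
  `λ − d`, which is float-unsafe) and breaks ties deterministically:
  diagonal, then the row-decreasing step, then the column step. Any
  optimal path has the same distance; the tie-break only fixes which one
  is reported.
- **Degenerate normalization.** If all candidates in Ω share one raw
  score, the min-max rescale is 0/0; all pairs then get s_h = 1 (equally,
  maximally supported).
- **Threshold sweeps.** Classification curves sweep ρ over {0} ∪ observed
  scores with the strict rule score > ρ; at thresholds with no positive
  classifications precision is taken as 1 (empty-prediction limit). AUPR
  and AUROC integrate trapezoidally along the threshold-descending path,
  so points tied in recall/FPR contribute zero width and AUROC equals the
  tie-aware rank statistic. The F-score at the precision-recall crossing
  is interpolated linearly in the threshold when no sweep point attains
  precision = recall exactly.
- **Annealer moves.** With probability ½ the partners of two random
  matched pairs are swapped (when both swapped pairs are admissible);
  otherwise one random node is reassigned to a random admissible free
  partner or unmatched. Acceptance is exp(Δf/T) for deteriorations. The
  best-so-far match set is returned, so the result never falls below the
  greedy seed; its score is recomputed from the score matrix at the end
  to avoid drift from incremental updates. The annealer's RNG is a
  self-contained Mersenne Twister seeded by an integer, so runs are
  bit-reproducible and independent of R's RNG state; master seeds fan out
  to per-network and per-alignment child seeds via `child_seeds()`.

## The synthetic benchmark: what it emulates, what it does not

The duplication–divergence generator mimics gene duplication (copy a node
with its links, optionally link duplicate to template with probability p)
followed by divergence (each duplicated link loses one of its two copies
with probability q), a standard model of PPI evolution producing
scale-free-like topology. Snapshots are growth stages recorded at fixed
step intervals — so network pairs from the same (p, q) regime share both
topology statistics and a growth trajectory. The benchmark labels
same-regime pairs positive and asks whether the normalized alignment
objective separates them; it measures *regime discrimination*, not
biological orthology recovery. Real PPI snapshots differ in ways the
generator does not emulate: measurement noise, confidence-weighted edges,
node sets that differ between species, and snapshot counts that vary per
condition. Passing the benchmark therefore shows the pipeline is
internally coherent and regime-sensitive at desk scale; it does not
certify alignment quality on any particular organism's data.

Divergence is applied to the *intersection* N(i) ∩ N(i′) immediately
after duplication — exactly the duplicated links, the standard reading —
and the optional (i, i′) link is never a divergence candidate. A
duplicate left without links is kept in the growth trace but is absent
from feature sequences (presence rule); it is not re-rolled, which would
bias the degree distribution.

## Noise schemes and the nestedness pitfall

Two randomization schemes perturb a dynamic network at level p.
*Temporal*: each edge, with probability p, swaps snapshots with a random
edge of a random other snapshot; swaps that would duplicate an edge in
their destination snapshot are resampled (bounded at 100 retries, then
skipped). This preserves every per-snapshot edge count **and** the
flattened (aggregated) network exactly — so a static aligner sees
literally the same input at every noise level, while a dynamic aligner
sees increasingly scrambled timing. *Structural*: the crossed rewiring
(a–b, c–d) → (a–d, b–c) across snapshots, with loop/duplicate proposals
undone and resampled; counts are preserved but the aggregate changes.

One consequence discovered while validating the schemes: on a **strictly
nested** snapshot sequence (each snapshot a superset of the previous, as
produced by `confidence_snapshots()` and, largely, by the growth
recorder), the duplicate-rejecting temporal swap is almost always
blocked — for e ∈ g_i and f ∈ g_j, nestedness puts f in g_i or e in g_j —
and the randomization degenerates to the identity. Noise experiments
therefore need a base network whose snapshots genuinely differ;
`transient_snapshots()` builds one by making each edge of a static
network present in each snapshot independently (every edge forced into at
least one snapshot, so the aggregate is preserved). With such a base the
package reproduces the expected qualitative contrast: the dynamic
alignment score decreases with temporal noise while the static score is
exactly constant, and both decrease under structural noise.

## Known limitations

- **Similarity underflow.** s_t = exp(−½λ²) with unnormalized λ reaches
  numerical 0 quickly: feature scales are unbounded (σ, η are raw
  counts), so λ is often in the tens-to-hundreds and the bulk of the
  similarity matrix is indistinguishable from 0. Discrimination then
  rides on the minority of near-zero-distance pairs. We keep the plain
  distance as the default because it is the method as defined, and expose
  `dtw_normalize` (divide λ by path length) for users who need a gentler
  scale; no bandwidth parameter is added to the Gaussian.
- **Mixed feature scales.** See above; no per-element standardization is
  applied.
- The annealer is a heuristic: optimality is verified exhaustively only
  at small sizes (the test suite does so on ≤ 6×6 instances); at
  benchmark sizes the greedy seed plus annealing is an approximation.
- Pairwise alignment only; multi-network match sets, directed or
  weighted-at-alignment-time snapshots, and continuous-time event streams
  are out of scope.
- Node correctness uses the aligner's output size as denominator by
  default (a precision); `denominator = "truth"` gives the recall-style
  variant. Both are exposed because the definition is ambiguous in
  common usage.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the full classification
experiment at 100-node networks, 5 snapshots, 10 networks per regime
(190 alignments, about two minutes), noise-trend experiments at 40-node
aggregates with 7 transient snapshots over 5 noise levels and 5 seeds,
and exhaustive-oracle checks at ≤ 6 nodes per side (annealer) and
sequence lengths ≤ 5 (warping paths). These sizes are the package's
chosen desk scale: large enough for the qualitative claims to be stable
across seeds, small enough to iterate on.
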