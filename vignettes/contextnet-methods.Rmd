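---
title: "contextnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{contextnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions the computations rest on, and why the genuinely open design
choices were resolved the way they were. Commands shown here are not
evaluated at build time; every empirical statement below is one the test
suite or `scripts/acceptance.R` computes itself.

## The analysis in one paragraph

Given several expression datasets per biological subcontext (tissue, cell
type, cell line), the pipeline produces one co-expression network per
subcontext whose edges are the top 1% of gene pairs by topological
overlap, then asks three families of questions: how do the networks relate
to each other (shared edges and nodes, commonality tiers), how do they
relate to a directed protein–protein interactome (edge overlap against
degree-preserving permutation nulls; structural controllability of the
interactome itself), and how do they relate to curated pathway gene sets
(fraction of a pathway's gene pairs realized as network edges, and
clustering of networks by those profiles).

## Preprocessing model

Each dataset is assumed to arrive as a normalized probes-by-samples
matrix on a single platform, already annotated with a subcontext label, a
usable flag, and a reference/control flag. Preprocessing is:

1. `filter_samples()` — keep usable reference/control samples only; the
   analysis characterises normal physiology, not perturbations.
2. `quantile_normalize()` — all samples of a dataset are forced onto the
   common distribution (row means of sorted columns; within-column ties
   get the mean of the quantile slots they span). Raw-array processing
   (background subtraction, CEL parsing) is deliberately out of scope:
   the package starts from normalized matrices.
3. `collapse_probes()` — one row per gene, keeping the probe with the
   largest sample variance. Ties break to the lexicographically smallest
   probe id so the collapse is bit-reproducible. The collapse is applied
   per dataset, after normalization and before merging: merging requires
   a common gene universe, and a per-dataset variance criterion does not
   let one dominating dataset decide every gene's probe. Whether collapse
   should instead happen after batch correction is a genuinely open
   ordering question; the per-dataset choice was made for determinism and
   order stability and is fixed.
4. `merge_by_subcontext()` — column concatenation over the
   *intersection* of gene sets (a single platform implies near-identical
   universes; intersection avoids imputation), with the source dataset
   recorded as the batch label.
5. `combat_adjust()` — parametric empirical-Bayes batch adjustment
   (normal prior on gene-wise batch locations, inverse-gamma on batch
   scales, no covariates), delegated to `sva::ComBat`. A single-batch
   matrix is returned unchanged; a batch with fewer than two samples is
   an error rather than a silent hazard.

Two numerical notes. First, the adjustment preserves each gene's pooled
mean only approximately: the scale step divides the shrunken residuals by
the posterior batch scale, which leaves an `O(σ/√n)` imprint on the
pooled mean (about `1e-4` at 100 samples per batch). The test suite
asserts preservation at `1e-3`, which the algebra supports; exact
preservation is not a property of the method. Second, the accuracy
contract the suite enforces is practical: a planted +3 two-batch shift at
100 samples per batch leaves a mean per-gene batch difference below 0.1
(the mean across genes — the per-gene maximum is dominated by sampling
noise of order `√(2/n) ≈ 0.14`, which no correction can remove).

## Network construction

`coexpression_network()` chains four operations:

- `correlation_matrix()` — Pearson correlation across samples (the
  conventional estimator for arrays; zero-variance genes are dropped with
  a warning, fewer than 3 samples is an error).
- `signed_adjacency()` — `a_ij = ((1 + cor_ij)/2)^β`. The signed
  transform keeps strong negative correlations near zero instead of
  letting them pose as connections. β defaults to 12, the conventional
  choice for signed networks; it is a config parameter, not an inferred
  quantity.
- `topological_overlap()` —
  `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)` with
  `l_ij = Σ_{u≠i,j} a_iu a_uj`, `k_i = Σ_{u≠i} a_iu`, diagonal 1. This is
  the standard unsigned TOM applied to the signed adjacency. The
  implementation is one matrix product (`l = A² − 2A` given unit
  diagonal); the suite checks it entrywise against a literal triple-loop
  evaluation at `|Δ| < 1e-12` and checks monotonicity in the adjacency
  numerically.
- `select_top_edges()` — exactly `round(fraction · n(n−1)/2)` pairs of
  highest TOM. Round-to-nearest is the declared rounding convention: at
  the 20,183-gene GPL570 universe and 1% it yields 2,036,667 edges
  (`top_edge_count(20183, 0.01)`), consistent with that platform's
  published network size. Ties at the cutoff break by lexicographic gene
  pair, so a network is a pure function of its TOM matrix.

Fixing the edge *count* rather than a weight threshold is what makes
networks of different subcontexts directly comparable; node counts are
then the quantity that varies (a network's node set is the union of its
edge endpoints).

## Controllability

`minimum_driver_count()` computes `N_D = max(N − |M|, 1)` from a maximum
matching `M` of the bipartite lift of the digraph (out-copy/in-copy per
node, one bipartite edge per arc). Any maximum-cardinality matching gives
the same `|M|`; the implementation uses `igraph::max_bipartite_match`,
and `brute_force_driver_count()` provides an independent exhaustive
oracle (branch-and-bound over edge subsets, ≤ 20 edges) against which the
suite checks 200 random digraphs, including all node and edge classes.
Node removal removes the node from the universe (the classification
compares against `N_D` of the N−1-node graph); unmatched in-copies name
one valid driver set, and when the matching is perfect the clamp to
`N_D = 1` means any single node serves. Edge removal can only shrink a
matching, so dispensable *edges* are structurally impossible; the class
is computed anyway and asserted empty, rather than assumed.

## Comparisons and permutation nulls

Edge sets are compared as canonical unordered-pair sets; interactome
direction is ignored on the co-expression side (`undirected_edges()`
collapses reciprocal arcs). Edge-commonality tiers use
`ceiling(tier · context_size)` as the membership threshold — the rounding
convention is declared, not derived. Networks are compared to the
interactome over their full edge sets, without first restricting to
interactome genes; restricting would change the observed and permuted
overlaps by the same censoring and the fold ratio only through edge
placement, and the unrestricted version is the simpler, declared choice.

`xswap()` draws degree-preserving permutations by repeated two-edge endpoint
swaps, rejecting self-loops and duplicates — delegated to igraph's
rewiring engine with an attempt budget of 10× the edge count, after which
edge-set Jaccard with the input drops well below 0.5 on networks of
realistic density (a property the suite tests). Degree multiset and edge
count are asserted on every call; a swap-locked graph (e.g. a triangle)
returns unchanged with a warning. `permutation_overlap_test()` reports
`fold_ratio = observed / mean(permuted)` and the add-one empirical
p-value `(1 + #{permuted ≥ observed}) / (n_perm + 1)` — the estimator
that cannot return 0 and is exact under exchangeability. A network drawn
from the null itself (one permutation of the original) calibrates at
fold ≈ 1 within Monte-Carlo error; the suite checks `[0.9, 1.1]` at 200
permutations. If the mean permuted overlap is 0 the ratio is reported as
0 with a `degenerate` flag rather than NaN.

## Pathway similarity and clustering

For pathway members `P` (size `m ≥ 2`) and network `N = (n′, E_N)`, the
score is `|{pairs of P that are edges of N}| / (m(m−1)/2)`. The
denominator deliberately counts *all* member pairs, including genes
absent from the network: a pathway only half-covered by the platform
cannot score 1, which keeps scores comparable across pathways. Networks
are clustered on Euclidean distances between their pathway-score rows
with average linkage (the linkage is configurable; average is the
default because single/complete are more tie-sensitive on near-duplicate
profiles). Rows are pre-sorted by label so tie-breaking is deterministic;
the suite checks the merge heights against a naive agglomeration oracle.

## The synthetic corpus: what it emulates, what it does not

`simulate_expression()` generates, per subcontext, several datasets
(= batches) under an equicorrelated single-factor model: genes of an
active module satisfy `x = √r·f + √(1−r)·ε`, giving exact latent pairwise
correlation `r` — chosen over richer covariance models precisely because
it yields a closed-form expectation to test against. Batch effects are
gene-wise additive shifts (`N(0, batch_shift_sd²)`) plus multiplicative
log-scale factors (`N(0, batch_scale_sd²)`) — the model the
empirical-Bayes adjustment assumes, which makes its parameter recovery
well-posed. Genes carry 1–`probes_per_gene_max` probes; probe 1 carries
the full signal with the smallest measurement noise while later probes
carry an attenuated (×0.5) signal with more noise, so "keep the most
variable probe" has a deterministic right answer (probe 1). Modules are
either shared (active in every subcontext — these genes are the
housekeeping ground truth) or specific to one subcontext, assigned
round-robin.

Default configuration (the package's declared study conditions): 1000
genes, 3 subcontexts × 3 datasets, 14/20/26 samples per dataset across
subcontexts (sizes vary, as they do in curated corpora, which keeps the
sample-count-versus-network-size correlation well-defined), 6 modules of
20 genes of which 2 are shared, `r = 0.8`, batch shift SD 1, log-scale SD
0.1, up to 2 probes per gene, noise SD 0.3. At these settings the
pooled-sample correlation of two same-module genes concentrates near
`0.8 / (1 + noise var) ≈ 0.73`, within-module pairs dominate the top TOM
ranks, and the top-1% networks recover essentially all active-module
pairs — the suite requires ≥ 80% over 5 seeds and observes ≈ 100%.

`simulate_interactome()` grows a simple directed graph by preferential
attachment to an exact edge count. Each node receives a source propensity
drawn from Beta(0.5, 0.5); the U-shape makes some proteins mostly
regulators and others mostly targets, producing zero-in-degree nodes and
hence a non-trivial driver-node set and all three controllability classes
— a homogeneous random digraph of the same density has a near-perfect
matching and a degenerate `N_D = 1`. Optionally a fraction (default 20%)
of edges is drawn from same-module gene pairs; without this coupling the
co-expression networks and the interactome would be independent by
construction and the observed-vs-permuted fold ratio would sit at 1 with
nothing to detect. `simulate_pathways()` draws half the sets from single
planted modules (high expected similarity on networks where the module is
active) and half uniformly (near-zero expected similarity at 1% density).

What the generator does **not** emulate: probe-sequence effects,
correlated (non-gene-wise) batch structure, dependence between module
membership and expression level, ontology structure among subcontexts,
and the literature bias that shapes real interactome degree
distributions. Passing recovery tests therefore demonstrates internal
consistency of the pipeline under its own assumptions, not performance on
raw GEO data.

## Reproducibility and problem sizes

All randomness flows from one master seed through `derive_seed(seed,
stage)` (a fixed integer hash folded into the seed modulo 2³¹−1), so any
stage can be re-run independently and byte-identically; the suite checks
on-disk determinism of both the generator and the full pipeline summary.
The shipped test suite and acceptance script run at deliberately desk
scale — 1000-gene universes, 400-node interactomes, 200–1000
permutations, oracle checks at n ≤ 20 — sizes chosen so the whole battery
re-runs in minutes while every oracle comparison remains exhaustive.
`scripts/acceptance.R --seed S --out f.json` recomputes the headline
quantities from scratch at those sizes.

## Known limitations

- The interface between raw arrays and the pipeline (RMA, CEL parsing,
  ontology-driven sample curation) is out of scope by design.
- ComBat is used without covariates and with parametric priors only;
  unbalanced designs with biological covariates confounded with batch
  need a different adjustment.
- β, the correlation estimator, the TOM variant and the cutoff tie policy
  are conventions, declared in configuration rather than estimated from
  data.
- `classify_nodes()` recomputes a maximum matching per node (O(N ·
  matching)); for interactomes far beyond 10⁴ nodes an incremental
  matching would be the next step, and must agree exactly.
- Network rendering (heatmaps, pie charts) is intentionally minimal:
  artifacts are TSV/JSON/Newick, ready for any plotting layer.
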