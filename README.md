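# contextnet

Transcriptomic co-expression is context-specific: the strongest gene–gene
correlations in liver are not those in cortex, and neither matches a
cancer cell line. `contextnet` is an R package for building and comparing
**context-specific gene co-expression networks** from multi-dataset
expression corpora, and for confronting them with a directed
protein–protein interactome and with pathway gene sets. It is aimed at
systems-biology researchers who want a tested, reproducible version of
this analysis rather than a pile of one-off scripts.

## What it computes

**Co-expression networks.** For each biological subcontext (a tissue, cell
type, or cell line measured by several datasets), the pipeline
quantile-normalizes each dataset, collapses probes to genes (most-variable
probe, deterministic tie-break), merges datasets, removes batch effects
with parametric empirical-Bayes adjustment (ComBat), and builds a signed
weighted network:

- signed adjacency `a_ij = ((1 + cor_ij) / 2)^β` (default β = 12),
- topological overlap
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
  `l_ij = Σ_u a_iu a_uj` and connectivity `k_i = Σ_u a_iu`,
- retention of exactly the top 1% of all gene pairs by TOM (for the
  20,183-gene GPL570 universe: 2,036,667 edges per network), so every
  network of a run has the same edge count and overlaps are directly
  comparable.

**Structural controllability of the interactome.** The minimum number of
driver nodes of the directed interactome is `N_D = max(N − |M|, 1)`, where
`|M|` is a maximum matching of the bipartite lift (arc `a→b` ↦ edge
`out(a)—in(b)`). Each node and edge is classified **indispensable /
dispensable / neutral** according to whether its removal increases,
decreases, or leaves `N_D` unchanged. An exhaustive brute-force matching
oracle is shipped for verification.

**Network comparison with permutation nulls.** Pairwise edge overlaps
within a context, edge-commonality tiers (unique, ≥25%, ≥50%, ≥75% of
networks), node commonality, and the overlap of each network with the
(undirected view of the) interactome, tested against degree-preserving
XSwap permutations: `fold_ratio = observed / mean(permuted)` with an
add-one empirical p-value.

**Pathway–network similarity.** For a pathway with member set of size `m`,
the score is the fraction of its `m(m−1)/2` unordered gene pairs that are
edges of the network; networks are hierarchically clustered (average
linkage, Euclidean distance) on their pathway-score profiles.

**Synthetic corpus generator.** A first-class module simulates the whole
study design — planted equicorrelated co-expression modules (shared or
subcontext-specific), additive/multiplicative batch effects, multi-probe
genes, a scale-free directed interactome, pathway gene sets and a
housekeeping list — with ground truth, so every stage is tested by
parameter recovery.

## Worked example

```r
library(contextnet)

cfg <- pipeline_config(
  output_dir = "demo_run",
  sim_config = simulation_config(n_genes = 300, n_modules = 4,
                                 module_size = 15, seed = 7),
  interactome_nodes = 150, interactome_edges = 1200,
  n_pathways = 20, n_perm = 200, seed = 7)
bundle <- run_pipeline(cfg)
pipeline_report(bundle)
```

```
## Networks

- sc1: 193 nodes, 448 edges
- sc2: 178 nodes, 448 edges
- sc3: 203 nodes, 448 edges
- samples-vs-nodes Pearson r: 0.397

## Interactome controllability

- driver nodes (N_D): 27
- indispensable: 8 nodes (5.33%)
- dispensable: 27 nodes (18.00%)
- neutral: 115 nodes (76.67%)

## Interactome overlap vs permuted networks

- sc1: observed 166, fold ratio 1.651, p = 0.004975
- sc2: observed 169, fold ratio 1.652, p = 0.004975
- sc3: observed 151, fold ratio 1.883, p = 0.004975
```

Every network keeps exactly `round(0.01 × 300·299/2) = 448` edges, so the
node counts (193/178/203) are the quantity that varies between
subcontexts. The three networks share about 1.7× as many edges with the
simulated interactome as their degree-preserving permutations do — the
planted co-expression modules are partly wired into the interactome, and
the permutation test detects exactly that excess. All artifacts
(edge lists, node statistics, controllability report, permutation JSON,
pathway similarity matrix, dendrogram) are written under `demo_run/`.

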