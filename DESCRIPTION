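Package: contextnet
Title: Context-Specific Gene Co-Expression Networks, Controllability, and
    Pathway Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-, cell-type-, and cell-line-specific gene
    co-expression networks from multi-dataset expression matrices (quantile
    normalisation, probe collapse, empirical-Bayes batch correction, signed
    adjacency, topological overlap, top-fraction edge selection), analyses a
    directed protein-protein interactome by structural controllability
    (minimum driver nodes via maximum matching; indispensable, dispensable
    and neutral node and edge classes), compares networks to each other and
    to the interactome with degree-preserving permutation null models, and
    scores networks against pathway gene sets with a pairwise edge-overlap
    similarity. Includes a synthetic-data generator with planted
    co-expression modules, batch effects, multi-probe genes, a scale-free
    interactome and matching pathway and housekeeping gene sets, used for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    sva,
    utils
Suggests:
    cluster,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
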