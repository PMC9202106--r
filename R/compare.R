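#' Edge overlap between two co-expression networks
#'
#' Number of unordered gene pairs present in both networks. All networks of
#' a run have the same edge count, so the raw count is comparable without
#' normalization.
#'
#' @param a,b `coexpression_network` objects.
#' @return Integer count of shared edges.
#' @export
pairwise_edge_overlap <- function(a, b) {
  length(intersect(network_edge_keys(a), network_edge_keys(b)))
}

#' Pairwise overlap matrix for a set of networks
#'
#' @param nets Named list of `coexpression_network` objects.
#' @return Symmetric integer matrix of shared-edge counts (diagonal = edge
#'   count of each network).
#' @export
overlap_matrix <- function(nets) {
  keys <- lapply(nets, network_edge_keys)
  labels <- names(nets) %||% vapply(nets, function(x) x$subcontext, character(1))
  n <- length(nets)
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <- length(intersect(keys[[i]], keys[[j]]))
  }
  m
}

#' Edge occurrence frequency across networks of one context
#'
#' Counts, for every edge in the union, how many networks contain it, and
#' summarizes commonality tiers over that union: unique edges (in at most
#' one network) and edges present in at least 25%, 50%, 75% of the networks
#' (thresholds are `ceiling(tier * context size)`).
#'
#' @param nets List of >= 2 `coexpression_network` objects.
#' @return Object of class `edge_frequency`: `table` (data.frame `gene_a`,
#'   `gene_b`, `count`), `context_size`, `n_unique`, `fraction_unique`,
#'   `tiers` (data.frame `tier`, `min_networks`, `n_edges`, `fraction`).
#' @export
edge_frequency <- function(nets) {
  if (length(nets) < 2) stop2("edge_frequency needs at least 2 networks")
  keys <- unlist(lapply(nets, network_edge_keys))
  tab <- table(keys)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  df <- data.frame(gene_a = vapply(parts, `[`, character(1), 1),
                   gene_b = vapply(parts, `[`, character(1), 2),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  k <- length(nets)
  total <- nrow(df)
  tiers <- data.frame(tier = c(0.25, 0.50, 0.75))
  tiers$min_networks <- ceiling(tiers$tier * k)
  tiers$n_edges <- vapply(tiers$min_networks, function(t) sum(df$count >= t),
                          integer(1))
  tiers$fraction <- tiers$n_edges / total
  structure(list(table = df, context_size = k,
                 n_unique = sum(df$count <= 1),
                 fraction_unique = sum(df$count <= 1) / total,
                 tiers = tiers),
            class = "edge_frequency")
}

#' Most and least common nodes across networks of one context
#'
#' @param nets List of >= 2 `coexpression_network` objects.
#' @return List with `in_all` (genes present in every network) and
#'   `in_exactly_one` (genes present in exactly one network), both sorted.
#' @export
node_commonality <- function(nets) {
  if (length(nets) < 2) stop2("node_commonality needs at least 2 networks")
  counts <- table(unlist(lapply(nets, `[[`, "nodes")))
  list(in_all = sort(names(counts)[counts == length(nets)]),
       in_exactly_one = sort(names(counts)[counts == 1]))
}

#' Edge overlap between a co-expression network and the interactome
#'
#' Direction is ignored on the interactome side, since co-expression edges
#' are inherently undirected.
#'
#' @param net A `coexpression_network`.
#' @param g Directed `igraph` interactome.
#' @return Integer count of shared unordered pairs.
#' @export
interactome_edge_overlap <- function(net, g) {
  length(intersect(network_edge_keys(net), interactome_edge_keys(g)))
}

#' Degree-preserving permutation of a network (XSwap)
#'
#' Repeatedly swaps the endpoints of random edge pairs
#' (`{a,b},{c,d} -> {a,d},{c,b}`), rejecting swaps that would create
#' self-loops or duplicate edges, so the permuted network has exactly the
#' original degree sequence and edge count. The attempt budget is
#' `n_swap_multiplier * |edges|`. A swap-locked network (e.g. a triangle)
#' is returned unchanged with a warning. Edge weights are dropped (set to
#' `NA`): they are meaningless after shuffling.
#'
#' @param net A `coexpression_network` with >= 2 edges.
#' @param n_swap_multiplier Swap attempts per edge (default 10).
#' @param seed Integer seed.
#' @return A permuted `coexpression_network`.
#' @export
xswap <- function(net, n_swap_multiplier = 10, seed = 1L) {
  if (nrow(net$edges) < 2) stop2("xswap needs at least 2 edges")
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  set.seed(derive_seed(seed, "xswap"))
  gp <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = n_swap_multiplier * nrow(net$edges)))
  el <- igraph::as_edgelist(gp)
  out <- build_network(data.frame(gene_a = pmin(el[, 1], el[, 2]),
                                  gene_b = pmax(el[, 1], el[, 2]),
                                  weight = NA_real_,
                                  stringsAsFactors = FALSE),
                       net$subcontext)
  # invariants asserted on every call
  d0 <- table(c(net$edges$gene_a, net$edges$gene_b))
  d1 <- table(c(out$edges$gene_a, out$edges$gene_b))
  stopifnot(nrow(out$edges) == nrow(net$edges),
            identical(sort(names(d0)), sort(names(d1))),
            all(d0[sort(names(d0))] == d1[sort(names(d0))]))
  if (setequal(network_edge_keys(out), network_edge_keys(net)))
    warning("xswap produced an identical network (swap-locked or unlucky run)")
  out
}

#' Permutation test of network-interactome edge overlap
#'
#' Compares the observed overlap with the interactome against `n_perm`
#' degree-preserving permutations of the network. The fold ratio is
#' `observed / mean(permuted)`; the empirical p-value uses the add-one
#' estimator `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param net A `coexpression_network`.
#' @param g Directed `igraph` interactome.
#' @param n_perm Number of permutations (default 1000).
#' @param n_swap_multiplier Swap attempts per edge per permutation.
#' @param seed Integer seed.
#' @return Object of class `permutation_result`: `observed`, `permuted`,
#'   `fold_ratio`, `empirical_p`, `degenerate` (TRUE when the mean permuted
#'   overlap is 0 and the ratio is reported as 0), `seed`.
#' @export
permutation_overlap_test <- function(net, g, n_perm = 1000,
                                     n_swap_multiplier = 10, seed = 1L) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  ikeys <- interactome_edge_keys(g)
  observed <- length(intersect(network_edge_keys(net), ikeys))
  base <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                        directed = FALSE)
  niter <- n_swap_multiplier * nrow(net$edges)
  set.seed(derive_seed(seed, "permutation_overlap_test"))
  permuted <- vapply(seq_len(n_perm), function(i) {
    gp <- igraph::rewire(base, igraph::keeping_degseq(loops = FALSE,
                                                      niter = niter))
    el <- igraph::as_edgelist(gp)
    length(intersect(edge_key(el[, 1], el[, 2]), ikeys))
  }, numeric(1))
  mu <- mean(permuted)
  degenerate <- mu == 0
  structure(list(observed = observed,
                 permuted = permuted,
                 fold_ratio = if (degenerate) 0 else observed / mu,
                 empirical_p = (1 + sum(permuted >= observed)) / (n_perm + 1),
                 degenerate = degenerate,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed=%d, mean permuted=%.2f, fold=%.3f, p=%.4g (n_perm=%d)\n",
              x$observed, mean(x$permuted), x$fold_ratio, x$empirical_p,
              length(x$permuted)))
  invisible(x)
}

#' Overlap of most/least common proteins with extreme-degree interactome nodes
#'
#' Ranks genes by how many networks of the context contain them (ties by
#' gene id) and takes the top `k` (most common) or bottom `k` among genes
#' present in at least one network (least common); intersects with the `k`
#' highest- (or lowest-) total-degree interactome nodes; annotates the
#' overlap with housekeeping membership and controllability class.
#'
#' @param nets List of `coexpression_network` objects.
#' @param g Directed `igraph` interactome.
#' @param k Set size per side (default 400); truncated with a warning when
#'   fewer genes are available.
#' @param end `"most"` or `"least"`.
#' @param housekeeping Optional housekeeping gene list.
#' @param node_class Optional named vector of controllability classes (from
#'   [classify_nodes()]).
#' @return data.frame `gene`, `n_networks`, `interactome_degree`,
#'   `housekeeping`, `class`.
#' @export
common_protein_degree_overlap <- function(nets, g, k = 400,
                                          end = c("most", "least"),
                                          housekeeping = character(),
                                          node_class = NULL) {
  end <- match.arg(end)
  if (k < 1) stop2("k must be >= 1")
  counts <- table(unlist(lapply(nets, `[[`, "nodes")))
  genes <- names(counts)
  if (k > length(genes) || k > igraph::gorder(g)) {
    warning("k exceeds available genes; truncating")
    k <- min(k, length(genes), igraph::gorder(g))
  }
  ord <- if (end == "most") order(-as.integer(counts), genes)
         else order(as.integer(counts), genes)
  top_genes <- genes[ord][seq_len(k)]
  deg <- igraph::degree(g, mode = "all")
  nodes <- igraph::V(g)$name
  dord <- if (end == "most") order(-deg, nodes) else order(deg, nodes)
  top_nodes <- nodes[dord][seq_len(k)]
  common <- sort(intersect(top_genes, top_nodes))
  data.frame(gene = common,
             n_networks = as.integer(counts[common]),
             interactome_degree = as.integer(deg[match(common, nodes)]),
             housekeeping = common %in% housekeeping,
             class = if (is.null(node_class)) NA_character_
                     else unname(node_class[common]),
             stringsAsFactors = FALSE)
}
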