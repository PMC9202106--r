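# Shared fixtures and independent oracles for the test suite.

# a small network from explicit pairs
toy_network <- function(pairs, subcontext = "toy", weight = NULL) {
  df <- data.frame(gene_a = vapply(pairs, `[`, character(1), 1),
                   gene_b = vapply(pairs, `[`, character(1), 2),
                   stringsAsFactors = FALSE)
  df$weight <- weight %||% rep(1, nrow(df))
  build_network(df, subcontext)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# random simple digraph on n nodes with edge probability p
rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
  pairs <- pairs[pairs$a != pairs$b, ]
  keep <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  edges <- if (nrow(keep) == 0)
    data.frame(from = character(0), to = character(0))
  else data.frame(from = paste0("v", keep$a), to = paste0("v", keep$b))
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = paste0("v", seq_len(n))))
}

# random undirected weighted network on a gene universe
rand_network <- function(n_genes, n_edges, seed, subcontext = "rand") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  ut <- utils::combn(genes, 2)
  pick <- sample(ncol(ut), n_edges)
  build_network(data.frame(gene_a = ut[1, pick], gene_b = ut[2, pick],
                           weight = runif(n_edges)), subcontext)
}

# O(n^3) literal TOM formula, triple loop
bf_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# brute-force betweenness by all-pairs shortest-path counting (not Brandes)
bf_betweenness <- function(g) {
  n <- igraph::gorder(g)
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(g, i, mode = "out")))
  # BFS from each source: distances and path counts
  dists <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dists[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dists[s, w])) {
          dists[s, w] <- dists[s, v] + 1
          nxt <- c(nxt, w)
        }
        if (dists[s, w] == dists[s, v] + 1)
          sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (is.finite(dists[s, t]) &&
        dists[s, v] + dists[v, t] == dists[s, t])
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  btw
}

# brute-force controllability classes via the exhaustive matching oracle
bf_classes <- function(g) {
  nd0 <- brute_force_driver_count(g)
  nm <- igraph::V(g)$name
  node_cls <- vapply(seq_along(nm), function(i) {
    nd1 <- brute_force_driver_count(igraph::delete_vertices(g, i))
    if (nd1 > nd0) "indispensable" else if (nd1 < nd0) "dispensable" else "neutral"
  }, character(1))
  el <- igraph::as_edgelist(g)
  edge_cls <- vapply(seq_len(nrow(el)), function(i) {
    nd1 <- brute_force_driver_count(igraph::delete_edges(g, i))
    if (nd1 > nd0) "indispensable" else if (nd1 < nd0) "dispensable" else "neutral"
  }, character(1))
  list(n_driver = nd0, node = stats::setNames(node_cls, nm),
       edge = edge_cls)
}

# naive average-linkage agglomeration on row vectors (independent of hclust):
# cluster distance = mean of all pairwise Euclidean row distances
naive_average_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# tiny default-shaped simulation config that runs fast
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 150, n_subcontexts = 3,
                    datasets_per_subcontext = 2, samples_per_dataset = 10,
                    n_modules = 3, module_size = 10,
                    shared_module_fraction = 1 / 3, seed = seed, ...)
}
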