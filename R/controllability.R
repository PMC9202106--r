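#' Minimum number of driver nodes of a directed network
#'
#' Structural controllability: a directed network can be fully controlled
#' through `N_D = max(N - |M|, 1)` driver nodes, where `|M|` is the size of
#' a maximum matching of the bipartite lift (every node split into an
#' out-copy and an in-copy; each arc `a -> b` becomes the bipartite edge
#' `out(a) -- in(b)`). Nodes whose in-copy is unmatched form one valid
#' driver set.
#'
#' @param g Directed `igraph` graph with at least one node.
#' @param return_drivers If `TRUE`, attach one valid driver-node set as the
#'   `drivers` attribute.
#' @return Integer driver-node count `N_D`.
#' @export
minimum_driver_count <- function(g, return_drivers = FALSE) {
  n <- igraph::gorder(g)
  if (n == 0) stop2("empty graph: controllability undefined")
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) {
    nd <- max(n, 1L)
    if (return_drivers) attr(nd, "drivers") <- igraph::V(g)$name %||% seq_len(n)
    return(nd)
  }
  # bipartite lift: vertices 1..n are out-copies, n+1..2n in-copies
  bg <- igraph::make_empty_graph(2L * n, directed = FALSE)
  bg <- igraph::add_edges(bg, as.vector(t(cbind(el[, 1], el[, 2] + n))))
  m <- igraph::max_bipartite_match(bg, types = rep(c(FALSE, TRUE), each = n))
  nd <- max(n - m$matching_size, 1L)
  if (return_drivers) {
    unmatched_in <- which(is.na(m$matching[(n + 1L):(2L * n)]))
    nm <- igraph::V(g)$name %||% as.character(seq_len(n))
    # perfect matching: N_D is clamped to 1 and any single node can serve
    attr(nd, "drivers") <- if (length(unmatched_in) == 0) nm[1]
                           else nm[unmatched_in]
  }
  nd
}

#' Classify nodes by their effect on controllability
#'
#' A node is indispensable if removing it (from the universe of N - 1
#' remaining nodes) increases the minimum driver count, dispensable if it
#' decreases it, and neutral otherwise.
#'
#' @param g Directed `igraph` graph with at least 2 nodes.
#' @return Named character vector: node -> one of `"indispensable"`,
#'   `"dispensable"`, `"neutral"`.
#' @export
classify_nodes <- function(g) {
  n <- igraph::gorder(g)
  if (n < 2) stop2("node classification needs at least 2 nodes")
  nd0 <- minimum_driver_count(g)
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  out <- character(n)
  for (i in seq_len(n)) {
    nd1 <- minimum_driver_count(igraph::delete_vertices(g, i))
    out[i] <- if (nd1 > nd0) "indispensable" else if (nd1 < nd0) "dispensable" else "neutral"
  }
  stats::setNames(out, nm)
}

#' Classify edges by their effect on controllability
#'
#' Same increase/decrease/no-change rule as [classify_nodes()], applied to
#' single-edge removal. Removing an edge can only shrink the maximum
#' matching, so structurally the dispensable class must be empty; it is
#' still computed for fidelity.
#'
#' @param g Directed `igraph` graph with at least 1 edge.
#' @return data.frame `from`, `to`, `class`.
#' @export
classify_edges <- function(g) {
  ne <- igraph::gsize(g)
  if (ne < 1) stop2("edge classification needs at least 1 edge")
  nd0 <- minimum_driver_count(g)
  el <- igraph::as_edgelist(g)
  cls <- character(ne)
  for (i in seq_len(ne)) {
    nd1 <- minimum_driver_count(igraph::delete_edges(g, i))
    cls[i] <- if (nd1 > nd0) "indispensable" else if (nd1 < nd0) "dispensable" else "neutral"
  }
  data.frame(from = el[, 1], to = el[, 2], class = cls,
             stringsAsFactors = FALSE)
}

#' Brute-force driver count (test oracle)
#'
#' Maximum matching of the bipartite lift by exhaustive branch-and-bound
#' over edge subsets that form a matching (no two chosen arcs sharing a
#' source or a target). Independent of the matching library; limited to 20
#' edges.
#'
#' @param g Directed `igraph` graph.
#' @return Integer driver-node count.
#' @export
brute_force_driver_count <- function(g) {
  n <- igraph::gorder(g)
  if (n == 0) stop2("empty graph: controllability undefined")
  el <- igraph::as_edgelist(g, names = FALSE)
  ne <- nrow(el)
  if (ne > 20) stop2("brute-force oracle limited to 20 edges")
  best <- 0L
  recurse <- function(i, used_src, used_dst, size) {
    if (size + (ne - i + 1L) <= best) return()  # cannot beat current best
    if (i > ne) { best <<- max(best, size); return() }
    s <- el[i, 1]; d <- el[i, 2]
    if (!(s %in% used_src) && !(d %in% used_dst))
      recurse(i + 1L, c(used_src, s), c(used_dst, d), size + 1L)
    recurse(i + 1L, used_src, used_dst, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  max(n - best, 1L)
}

#' Full controllability report
#'
#' Driver-node count, per-node and per-edge classes, class counts and
#' percentages for a directed interactome.
#'
#' @param g Directed `igraph` graph (>= 2 nodes, >= 1 edge).
#' @param classify_edges_too Compute edge classes as well (default `TRUE`).
#' @return Object of class `controllability_report`: `n_driver`, `drivers`,
#'   `node_class`, `node_counts`, `node_percentages`, and (optionally)
#'   `edge_class`, `edge_counts`.
#' @export
controllability_report <- function(g, classify_edges_too = TRUE) {
  nd <- minimum_driver_count(g, return_drivers = TRUE)
  node_class <- classify_nodes(g)
  lv <- c("indispensable", "dispensable", "neutral")
  counts <- table(factor(node_class, levels = lv))
  pct <- 100 * as.numeric(counts) / length(node_class)
  out <- list(n_driver = as.integer(nd),
              drivers = attr(nd, "drivers"),
              node_class = node_class,
              node_counts = stats::setNames(as.integer(counts), lv),
              node_percentages = stats::setNames(pct, lv))
  if (classify_edges_too) {
    ec <- classify_edges(g)
    out$edge_class <- ec
    out$edge_counts <- stats::setNames(
      as.integer(table(factor(ec$class, levels = lv))), lv)
  }
  structure(out, class = "controllability_report")
}

#' @export
print.controllability_report <- function(x, ...) {
  cat(sprintf("<controllability_report> N_D = %d\n", x$n_driver))
  for (cl in names(x$node_counts))
    cat(sprintf("  %-13s %6d nodes (%5.2f%%)\n", cl, x$node_counts[[cl]],
                x$node_percentages[[cl]]))
  invisible(x)
}
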