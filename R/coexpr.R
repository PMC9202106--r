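#' Gene-gene Pearson correlation matrix
#'
#' Correlation of gene expression profiles across samples. Genes with zero
#' variance carry no correlation information and are dropped with a warning.
#'
#' @param m A [gene_expression()] object or a genes-by-samples matrix.
#' @param min_samples Minimum number of samples required (default 3).
#' @return Symmetric genes-by-genes matrix in \[-1, 1\] with unit diagonal.
#' @export
correlation_matrix <- function(m, min_samples = 3) {
  values <- if (inherits(m, "gene_expression")) m$values else as.matrix(m)
  if (ncol(values) < min_samples)
    stop2("need at least ", min_samples, " samples to estimate correlations")
  v <- apply(values, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(values)[v == 0], 5), collapse = ", "))
    values <- values[v > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(values))
  diag(cc) <- 1
  cc
}

#' Signed soft-threshold adjacency
#'
#' The signed transform `a_ij = ((1 + cor_ij) / 2)^beta` maps correlation
#' -1 to 0 and +1 to 1, so strong negative correlations do not masquerade as
#' connections; `beta` soft-thresholds weak correlations towards zero.
#'
#' @param cor_mat Symmetric correlation matrix in \[-1, 1\].
#' @param beta Soft-thresholding power, > 0 (default 12, the conventional
#'   signed-network choice).
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta = 12) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop2("beta must be a positive number")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu * a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; diagonal set to 1. High topological overlap
#' means two genes are strongly linked both directly and through shared
#' neighbours.
#'
#' @param a Adjacency matrix (symmetric, \[0, 1\], unit diagonal).
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8)
    stop2("adjacency must be a symmetric square matrix")
  diag(a) <- 1
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a            # removes u = i and u = j terms (diag = 1)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Number of edges retained by a top-fraction rule
#'
#' For `n` genes there are `n (n - 1) / 2` unordered pairs; the network
#' keeps the `round(fraction * pairs)` pairs of highest topological overlap.
#' For the 20,183 genes measured by the GPL570 platform and the default 1%
#' rule this is 2,036,667 edges.
#'
#' @param n_genes Number of genes.
#' @param fraction Fraction of pairs to retain, in (0, 1].
#' @return Integer edge count.
#' @export
top_edge_count <- function(n_genes, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop2("fraction must be in (0, 1]")
  if (n_genes < 2) stop2("need at least 2 genes")
  round(fraction * n_genes * (n_genes - 1) / 2)
}

#' Select the top fraction of TOM pairs
#'
#' Retains exactly [top_edge_count()] unordered pairs with the largest TOM
#' values. Ties at the cutoff are broken by lexicographic gene-pair order;
#' the result is sorted by weight descending.
#'
#' @param tom Symmetric TOM matrix with gene dimnames.
#' @param fraction Fraction of all pairs to keep (default 0.01).
#' @return data.frame `gene_a`, `gene_b`, `weight` with
#'   `gene_a < gene_b` lexicographically.
#' @export
select_top_edges <- function(tom, fraction = 0.01) {
  tom <- as.matrix(tom)
  n <- nrow(tom)
  if (n < 2) stop2("need at least 2 genes")
  genes <- rownames(tom) %||% sprintf("g%04d", seq_len(n))
  n_keep <- top_edge_count(n, fraction)
  ut <- which(upper.tri(tom))
  w <- tom[ut]
  i <- ((ut - 1) %% n) + 1
  j <- ((ut - 1) %/% n) + 1
  a <- pmin(genes[i], genes[j])
  b <- pmax(genes[i], genes[j])
  ord <- order(-w, a, b)[seq_len(n_keep)]
  data.frame(gene_a = a[ord], gene_b = b[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' Assemble a co-expression network
#'
#' @param edges data.frame `gene_a`, `gene_b`, `weight` (unordered pairs;
#'   canonicalized so `gene_a < gene_b`).
#' @param subcontext Subcontext label.
#' @return Object of class `coexpression_network`: `subcontext`, `edges`,
#'   `nodes` (sorted union of edge endpoints).
#' @export
build_network <- function(edges, subcontext) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  if (nrow(edges) == 0) stop2("a network needs at least one edge")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  if (any(a == b)) stop2("self-pairs are not allowed")
  ed <- data.frame(gene_a = a, gene_b = b,
                   weight = edges$weight %||% rep(NA_real_, nrow(edges)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(edge_key(ed$gene_a, ed$gene_b)))
    stop2("duplicate edges")
  structure(list(subcontext = subcontext, edges = ed,
                 nodes = sort(unique(c(a, b)))),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %s: %d nodes, %d edges\n",
              x$subcontext, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Edge keys of a co-expression network
#' @param net A `coexpression_network`.
#' @return Character vector of canonical pair keys.
#' @keywords internal
network_edge_keys <- function(net) {
  edge_key(net$edges$gene_a, net$edges$gene_b)
}

#' Build the co-expression network of one subcontext
#'
#' Full chain from a batch-corrected expression matrix to the retained
#' network: correlation, signed adjacency, topological overlap, top-fraction
#' edge selection.
#'
#' @param m A [gene_expression()].
#' @param beta Soft-thresholding power (default 12).
#' @param fraction Top fraction of pairs to keep (default 0.01).
#' @return A `coexpression_network`.
#' @export
coexpression_network <- function(m, beta = 12, fraction = 0.01) {
  tom <- topological_overlap(signed_adjacency(correlation_matrix(m), beta))
  build_network(select_top_edges(tom, fraction),
                if (inherits(m, "gene_expression")) m$subcontext else "network")
}

#' Write / read a network edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight` (`gene_a < gene_b`), plus a
#' JSON sidecar recording the subcontext and the construction parameters.
#'
#' @param net A `coexpression_network`.
#' @param path Edge-list TSV path (sidecar gets `.json` appended).
#' @param beta,fraction Parameters echoed into the sidecar.
#' @return `read_network` returns a `coexpression_network`.
#' @export
write_network <- function(net, path, beta = NA, fraction = NA) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(subcontext = net$subcontext, n_nodes = length(net$nodes),
         n_edges = nrow(net$edges), beta = beta, fraction = fraction),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @param subcontext Label for the network read back (defaults to the
#'   sidecar's label when present).
#' @export
read_network <- function(path, subcontext = NULL) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.null(subcontext)) {
    sidecar <- paste0(path, ".json")
    subcontext <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar)$subcontext else "network"
  }
  build_network(ed, subcontext)
}
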