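#' Read a directed interactome from an edge-list TSV
#'
#' Expects a header line with at least `source` and `target` columns (an
#' optional `relation` column is carried along as an edge attribute).
#' Self-loops are dropped and duplicate directed edges collapsed, each with a
#' warning; a malformed row is an error naming its line number.
#'
#' @param path TSV file path.
#' @return A directed `igraph` graph.
#' @export
read_interactome <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop2("empty interactome file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  si <- match("source", header); ti <- match("target", header)
  if (is.na(si) || is.na(ti))
    stop2("interactome header must contain 'source' and 'target'")
  n_min <- max(si, ti)
  body <- fields[-1]
  for (i in seq_along(body)) {
    if (length(body[[i]]) < n_min || !nzchar(body[[i]][si]) || !nzchar(body[[i]][ti]))
      stop2("malformed interactome row at line ", i + 1)
  }
  src <- vapply(body, `[`, character(1), si)
  dst <- vapply(body, `[`, character(1), ti)
  loops <- src == dst
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    src <- src[!loops]; dst <- dst[!loops]
  }
  key <- paste0(src, ">", dst)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate directed edge(s) collapsed")
    keep <- !duplicated(key)
    src <- src[keep]; dst <- dst[keep]
  }
  igraph::graph_from_data_frame(
    data.frame(from = src, to = dst, stringsAsFactors = FALSE),
    directed = TRUE)
}

#' Write an interactome as an edge-list TSV
#'
#' @param g Directed `igraph` graph.
#' @param path Output path. Columns `source`, `target`, `directed`; edges
#'   sorted for a canonical byte-stable file.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], target = el[, 2], directed = TRUE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Undirected view of a directed interactome
#'
#' Co-expression edges are undirected, so comparisons against the
#' interactome ignore direction: the pair `{a, b}` is included once if
#' either `a -> b` or `b -> a` exists.
#'
#' @param g Directed `igraph` graph.
#' @return data.frame `gene_a`, `gene_b` (canonical order), one row per
#'   unordered pair.
#' @export
undirected_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  keep <- !duplicated(paste(a, b, sep = "|"))
  data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
}

#' Undirected interactome edges as canonical keys
#' @keywords internal
interactome_edge_keys <- function(g) {
  ue <- undirected_edges(g)
  edge_key(ue$gene_a, ue$gene_b)
}

#' Per-node statistics of the interactome
#'
#' Total degree (in + out), shortest-path betweenness on the directed graph
#' min-max scaled to \[0, 1\] for comparability, and a housekeeping flag by
#' list membership.
#'
#' @param g Directed `igraph` graph.
#' @param housekeeping Character vector of housekeeping gene ids (optional).
#' @return data.frame `node`, `degree`, `betweenness_scaled`, `housekeeping`.
#' @export
node_statistics <- function(g, housekeeping = character()) {
  deg <- igraph::degree(g, mode = "all")
  btw <- igraph::betweenness(g, directed = TRUE)
  rng <- range(btw)
  scaled <- if (diff(rng) == 0) rep(0, length(btw)) else (btw - rng[1]) / diff(rng)
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(deg),
             betweenness_scaled = as.numeric(scaled),
             housekeeping = igraph::V(g)$name %in% housekeeping,
             stringsAsFactors = FALSE)
}

#' Housekeeping genes present in the interactome
#'
#' @param g Directed `igraph` graph.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @return List with `count` (housekeeping genes that are interactome nodes)
#'   and `fraction` (count / number of nodes).
#' @export
housekeeping_overlap <- function(g, housekeeping) {
  count <- sum(unique(housekeeping) %in% igraph::V(g)$name)
  list(count = count, fraction = count / igraph::gorder(g))
}
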