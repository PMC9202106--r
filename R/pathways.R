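#' Read pathway gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are deduplicated with a warning; a line
#' with fewer than 3 fields is an error naming the line number.
#'
#' @param path GMT file path.
#' @return List of `pathway_gene_set` objects (`id`, `name`, `members`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop2("GMT line ", i, " has fewer than 3 fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    out[[i]] <- structure(list(id = f[1], name = f[2], members = sort(members)),
                          class = "pathway_gene_set")
  }
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop2("duplicate gene-set ids in GMT file")
  out
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways List of `pathway_gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$id, p$name, p$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway-network similarity
#'
#' For a pathway with member set of size `m`, the candidate pair set `C_n`
#' holds all `m (m - 1) / 2` unordered member pairs. The edge overlap counts
#' the pairs of `C_n` whose both genes occur in the network and which are
#' edges of the network; the similarity is `edge overlap / |C_n|`, in
#' \[0, 1\]. The denominator runs over all member pairs, so pathways only
#' partly covered by the expression platform are penalized rather than
#' rescaled.
#'
#' @param pathway A `pathway_gene_set` or a character vector of >= 2 gene
#'   ids.
#' @param net A `coexpression_network`.
#' @return Similarity score in \[0, 1\].
#' @export
pathway_network_similarity <- function(pathway, net) {
  members <- if (inherits(pathway, "pathway_gene_set")) pathway$members
             else unique(as.character(pathway))
  m <- length(members)
  if (m < 2) stop2("pathway needs at least 2 members")
  hit <- net$edges$gene_a %in% members & net$edges$gene_b %in% members
  sum(hit) / (m * (m - 1) / 2)
}

#' Networks-by-pathways similarity matrix
#'
#' @param nets Named list of `coexpression_network` objects.
#' @param pathways List of `pathway_gene_set` objects; sets with fewer than
#'   2 members are skipped with a warning.
#' @return Numeric matrix, rows = networks, columns = pathways, values in
#'   \[0, 1\].
#' @export
similarity_matrix <- function(nets, pathways) {
  if (length(nets) < 1) stop2("need at least one network")
  sizes <- vapply(pathways, function(p) length(p$members), integer(1))
  if (any(sizes < 2)) {
    warning(sum(sizes < 2), " pathway(s) with < 2 members skipped")
    pathways <- pathways[sizes >= 2]
  }
  if (length(pathways) < 1) stop2("no scoreable pathway")
  rown <- names(nets) %||% vapply(nets, `[[`, character(1), "subcontext")
  coln <- vapply(pathways, `[[`, character(1), "id")
  m <- matrix(0, length(nets), length(pathways),
              dimnames = list(rown, coln))
  for (i in seq_along(nets)) for (j in seq_along(pathways))
    m[i, j] <- pathway_network_similarity(pathways[[j]], nets[[i]])
  m
}

#' Hierarchically cluster networks by their pathway-similarity profiles
#'
#' Agglomerative clustering on the Euclidean distances between network rows
#' of the similarity matrix. Rows are pre-sorted by label so that distance
#' ties resolve deterministically.
#'
#' @param m Networks-by-pathways similarity matrix.
#' @param linkage Linkage method for [stats::hclust] (default
#'   `"average"`).
#' @return List: `order` (network labels in dendrogram order), `heights`
#'   (merge heights), `hclust` (the full `hclust` object), `newick`
#'   (dendrogram as a Newick string).
#' @export
cluster_networks <- function(m, linkage = "average") {
  if (nrow(m) < 2) stop2("clustering needs at least 2 networks")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
  list(order = rownames(m)[hc$order],
       heights = hc$height,
       hclust = hc,
       newick = .hclust_newick(hc))
}

# hclust merge table -> Newick string with branch heights
.hclust_newick <- function(hc) {
  lab <- hc$labels
  render <- function(i) {
    if (i < 0) lab[-i]
    else {
      h <- hc$height[i]
      kids <- hc$merge[i, ]
      paste0("(", render(kids[1]), ":", format(h, digits = 6), ",",
             render(kids[2]), ":", format(h, digits = 6), ")")
    }
  }
  paste0(render(nrow(hc$merge)), ";")
}
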