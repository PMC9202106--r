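#' Keep usable reference/control samples
#'
#' The analysis characterises the normal physiological state of each
#' subcontext, so only samples flagged both usable and reference/control are
#' retained. Row order is preserved; an empty result is allowed.
#'
#' @param metadata data.frame with logical columns `usable` and
#'   `is_reference` (one row per sample).
#' @return The filtered data.frame.
#' @export
filter_samples <- function(metadata) {
  stopifnot(is.data.frame(metadata))
  if (nrow(metadata) == 0) return(metadata)
  if (!all(c("usable", "is_reference") %in% names(metadata)))
    stop2("metadata must have 'usable' and 'is_reference' columns")
  if (anyDuplicated(metadata$sample_id))
    stop2("duplicate sample ids in metadata")
  metadata[metadata$usable & metadata$is_reference, , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution: the
#' row-wise mean of the per-column sorted values. Ties within a column
#' receive the mean of the quantile values they span.
#'
#' @param m Numeric probes-by-samples matrix; all values finite.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1) stop2("quantile_normalize needs at least one sample")
  if (!all(is.finite(m))) stop2("non-finite values in expression matrix")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probes to genes by maximal variance
#'
#' When several probes measure the same gene, the probe with the largest
#' sample variance is kept as that gene's row; probes absent from the map are
#' dropped. Variance ties are broken by the lexicographically smallest probe
#' id, making the collapse deterministic.
#'
#' @param m Numeric probes-by-samples matrix (rownames = probe ids).
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; a probe
#'   mapped to more than one gene is an error.
#' @return Genes-by-samples matrix, gene rows sorted by gene id.
#' @export
collapse_probes <- function(m, probe_map) {
  m <- as.matrix(m)
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  multi <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  if (length(multi) > 0) {
    bad <- multi[vapply(multi, function(p)
      length(unique(probe_map$gene_id[probe_map$probe_id == p])) > 1, logical(1))]
    if (length(bad) > 0)
      stop2("probe mapped to multiple genes: ", paste(bad, collapse = ", "))
  }
  probe_map <- probe_map[!duplicated(probe_map$probe_id), , drop = FALSE]
  keep <- intersect(rownames(m), probe_map$probe_id)
  if (length(keep) == 0) stop2("no probes of the matrix occur in the probe map")
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)[keep]
  v <- apply(m[keep, , drop = FALSE], 1, stats::var)
  ord <- order(gene_of, -v, keep)  # per gene: max variance, then lexicographic
  picked <- keep[ord][!duplicated(gene_of[ord])]
  out <- m[picked, , drop = FALSE]
  rownames(out) <- gene_of[picked]
  out[order(rownames(out)), , drop = FALSE]
}

#' A gene expression matrix with batch labels
#'
#' Light S3 container for a merged, gene-level subcontext matrix.
#'
#' @param values Genes-by-samples numeric matrix.
#' @param batch Character vector of batch (dataset) labels, one per sample
#'   (named by sample id).
#' @param subcontext Subcontext label.
#' @return Object of class `gene_expression`.
#' @export
gene_expression <- function(values, batch, subcontext) {
  stopifnot(is.matrix(values), length(batch) == ncol(values))
  if (anyDuplicated(rownames(values))) stop2("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop2("duplicate sample ids")
  structure(list(values = values,
                 batch = stats::setNames(as.character(batch), colnames(values)),
                 subcontext = subcontext),
            class = "gene_expression")
}

#' @export
print.gene_expression <- function(x, ...) {
  cat(sprintf("<gene_expression> subcontext=%s: %d genes x %d samples, %d batch(es)\n",
              x$subcontext, nrow(x$values), ncol(x$values),
              length(unique(x$batch))))
  invisible(x)
}

#' Merge gene-level datasets of one subcontext
#'
#' Column-binds all samples over the intersection of the gene sets, recording
#' the source dataset of each sample as its batch label. Sample-id collisions
#' across datasets are resolved by prefixing the dataset id.
#'
#' @param datasets Named list of genes-by-samples matrices (names = dataset
#'   ids), or a list of `list(values=, dataset_id=)` entries.
#' @param subcontext Subcontext label for the merged matrix.
#' @return A [gene_expression()] object.
#' @export
merge_by_subcontext <- function(datasets, subcontext) {
  if (length(datasets) == 0) stop2("no datasets to merge")
  mats <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (is.list(d) && !is.null(d$values)) d$values else as.matrix(d)
  })
  ids <- names(datasets)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(seq_along(datasets), function(i)
      datasets[[i]]$dataset_id %||% paste0("ds", i), character(1))
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0) stop2("empty gene intersection across datasets")
  common <- sort(common)
  all_samples <- unlist(lapply(mats, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  pieces <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]][common, , drop = FALSE]
    clash <- colnames(m) %in% dup
    colnames(m)[clash] <- paste(ids[i], colnames(m)[clash], sep = ".")
    m
  })
  values <- do.call(cbind, pieces)
  batch <- rep(ids, vapply(mats, ncol, integer(1)))
  gene_expression(values, batch, subcontext)
}

#' Empirical-Bayes batch correction
#'
#' Adjusts gene-wise additive and multiplicative batch effects with the
#' parametric empirical-Bayes model (normal prior on batch location,
#' inverse-gamma on batch scale; no covariates), via [sva::ComBat]. A
#' single-batch matrix is returned unchanged; with two or more batches every
#' batch must contribute at least two samples.
#'
#' @param m A [gene_expression()] object.
#' @return A `gene_expression` with the same shape, sample ids and batches.
#' @export
combat_adjust <- function(m) {
  stopifnot(inherits(m, "gene_expression"))
  batches <- unique(m$batch)
  if (length(batches) < 2) return(m)
  sizes <- table(m$batch)
  if (any(sizes < 2))
    stop2("batch with fewer than 2 samples: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  adj <- suppressMessages(
    sva::ComBat(dat = m$values, batch = m$batch, mod = NULL,
                par.prior = TRUE, prior.plots = FALSE))
  dimnames(adj) <- dimnames(m$values)
  gene_expression(adj, m$batch, m$subcontext)
}

#' Run the preprocessing chain for one subcontext
#'
#' Quantile-normalizes each dataset, collapses probes to genes per dataset,
#' merges all datasets of the subcontext, and batch-corrects the merged
#' matrix.
#'
#' @param datasets Named list of probe-level matrices (or
#'   `list(values=, dataset_id=)` entries) belonging to one subcontext.
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param subcontext Subcontext label.
#' @return A batch-corrected [gene_expression()].
#' @export
preprocess_subcontext <- function(datasets, probe_map, subcontext) {
  gene_level <- lapply(datasets, function(d) {
    v <- if (is.list(d) && !is.null(d$values)) d$values else as.matrix(d)
    collapse_probes(quantile_normalize(v), probe_map)
  })
  names(gene_level) <- names(datasets)
  combat_adjust(merge_by_subcontext(gene_level, subcontext))
}
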