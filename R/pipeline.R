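#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. With `data_dir = NULL` the
#' pipeline generates its own synthetic corpus, interactome, pathways and
#' housekeeping list from `sim_config`; otherwise it reads the plain-text
#' exchange formats from disk.
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param data_dir Optional directory with an existing corpus (expression
#'   TSVs + `metadata.tsv` + `probe_map.tsv`).
#' @param interactome_path,pathways_path,housekeeping_path Optional paths;
#'   required when `data_dir` is given.
#' @param sim_config A [simulation_config()] used when simulating.
#' @param beta Soft-threshold power for the signed adjacency.
#' @param fraction Top fraction of TOM pairs kept as edges.
#' @param n_perm Permutations for the interactome-overlap test.
#' @param n_swap_multiplier XSwap attempts per edge.
#' @param k Set size for the most/least-common protein comparison.
#' @param linkage Linkage for network clustering.
#' @param interactome_nodes,interactome_edges Size of the simulated
#'   interactome (nodes are drawn from the gene universe).
#' @param n_pathways Number of simulated pathways.
#' @param seed Master seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("contextnet_run_"),
                            data_dir = NULL,
                            interactome_path = NULL,
                            pathways_path = NULL,
                            housekeeping_path = NULL,
                            sim_config = simulation_config(),
                            beta = 12,
                            fraction = 0.01,
                            n_perm = 1000,
                            n_swap_multiplier = 10,
                            k = 400,
                            linkage = "average",
                            interactome_nodes = 400,
                            interactome_edges = 4000,
                            n_pathways = 40,
                            seed = 1L) {
  structure(list(output_dir = output_dir, data_dir = data_dir,
                 interactome_path = interactome_path,
                 pathways_path = pathways_path,
                 housekeeping_path = housekeeping_path,
                 sim_config = sim_config, beta = beta, fraction = fraction,
                 n_perm = n_perm, n_swap_multiplier = n_swap_multiplier,
                 k = k, linkage = linkage,
                 interactome_nodes = interactome_nodes,
                 interactome_edges = interactome_edges,
                 n_pathways = n_pathways, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full context-specific network pipeline
#'
#' Stages: (1) simulate or load the multi-dataset corpus; (2) preprocess
#' each subcontext (quantile normalization, probe collapse, merge, batch
#' correction); (3) build one signed-TOM co-expression network per
#' subcontext; (4) network comparisons (pairwise overlaps, edge-frequency
#' tiers, node commonality); (5) interactome statistics and structural
#' controllability; (6) permutation tests of network-interactome overlap;
#' (7) pathway similarity matrix and network clustering. Writes all
#' artifacts plus a JSON summary (including the correlation between a
#' subcontext's sample count and its network node count, a standard
#' size-bias check).
#'
#' @param config A [pipeline_config()].
#' @return The report bundle (named list of all stage results), invisibly;
#'   artifacts are written under `config$output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # ---- stage: data ---------------------------------------------------------
  if (is.null(config$data_dir)) {
    sim_cfg <- config$sim_config
    sim_cfg$seed <- derive_seed(seed, "corpus")
    sim <- simulate_expression(sim_cfg)
    planted <- sim$planted
    gi <- sort(sample_genes_for_interactome(planted, config$interactome_nodes,
                                            derive_seed(seed, "interactome_nodes")))
    interactome <- simulate_interactome(length(gi), config$interactome_edges,
                                        seed = derive_seed(seed, "interactome"),
                                        node_ids = gi, planted = planted)
    pathways <- simulate_pathways(planted, config$n_pathways,
                                  seed = derive_seed(seed, "pathways"))
    housekeeping <- simulate_housekeeping(planted)
  } else {
    sim <- load_corpus(config$data_dir)
    planted <- NULL
    interactome <- read_interactome(config$interactome_path)
    pathways <- read_gmt(config$pathways_path)
    housekeeping <- read_housekeeping(config$housekeeping_path)
  }

  # ---- stage: preprocess + networks ---------------------------------------
  meta <- filter_samples(sim$metadata)
  subcontexts <- unique(meta$subcontext)
  nets <- list()
  merged <- list()
  samples_per_sc <- integer(0)
  for (sc in subcontexts) {
    ds_ids <- unique(meta$dataset_id[meta$subcontext == sc])
    datasets <- lapply(sim$datasets[ds_ids], function(d) {
      keep <- intersect(colnames(d$values), meta$sample_id)
      list(values = d$values[, keep, drop = FALSE], dataset_id = d$dataset_id)
    })
    names(datasets) <- ds_ids
    expr <- preprocess_subcontext(datasets, sim$probe_map, sc)
    merged[[sc]] <- expr
    samples_per_sc[sc] <- ncol(expr$values)
    nets[[sc]] <- coexpression_network(expr, beta = config$beta,
                                       fraction = config$fraction)
    write_network(nets[[sc]], file.path(config$output_dir,
                                        paste0("network_", sc, ".tsv")),
                  beta = config$beta, fraction = config$fraction)
  }

  # ---- stage: compare ------------------------------------------------------
  ovl <- overlap_matrix(nets)
  utils::write.table(ovl, file.path(config$output_dir, "network_overlap.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  freq <- edge_frequency(nets)
  utils::write.table(freq$table,
                     file.path(config$output_dir, "edge_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  commonality <- node_commonality(nets)

  # ---- stage: interactome + controllability -------------------------------
  write_interactome(interactome, file.path(config$output_dir, "interactome.tsv"))
  stats_tab <- node_statistics(interactome, housekeeping)
  hk_overlap <- housekeeping_overlap(interactome, housekeeping)
  ctrl <- controllability_report(interactome, classify_edges_too = TRUE)
  stats_tab$class <- unname(ctrl$node_class[stats_tab$node])
  utils::write.table(stats_tab, file.path(config$output_dir, "node_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_driver = ctrl$n_driver, node_counts = as.list(ctrl$node_counts),
         node_percentages = as.list(ctrl$node_percentages),
         edge_counts = as.list(ctrl$edge_counts)),
    file.path(config$output_dir, "controllability.json"),
    auto_unbox = TRUE, pretty = TRUE)

  # ---- stage: permutation tests -------------------------------------------
  perms <- lapply(seq_along(nets), function(i)
    permutation_overlap_test(nets[[i]], interactome, n_perm = config$n_perm,
                             n_swap_multiplier = config$n_swap_multiplier,
                             seed = derive_seed(seed, paste0("perm_", names(nets)[i]))))
  names(perms) <- names(nets)
  jsonlite::write_json(
    lapply(perms, function(p) list(observed = p$observed,
                                   mean_permuted = mean(p$permuted),
                                   fold_ratio = p$fold_ratio,
                                   empirical_p = p$empirical_p)),
    file.path(config$output_dir, "permutation_tests.json"),
    auto_unbox = TRUE, pretty = TRUE)

  # ---- stage: common proteins ---------------------------------------------
  common_most <- common_protein_degree_overlap(
    nets, interactome, k = min(config$k, igraph::gorder(interactome)),
    end = "most", housekeeping = housekeeping, node_class = ctrl$node_class)
  common_least <- common_protein_degree_overlap(
    nets, interactome, k = min(config$k, igraph::gorder(interactome)),
    end = "least", housekeeping = housekeeping, node_class = ctrl$node_class)

  # ---- stage: pathways -----------------------------------------------------
  write_gmt(pathways, file.path(config$output_dir, "pathways.gmt"))
  simmat <- similarity_matrix(nets, pathways)
  utils::write.table(simmat,
                     file.path(config$output_dir, "pathway_similarity.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  clustering <- if (length(nets) >= 2)
    cluster_networks(simmat, linkage = config$linkage) else NULL
  if (!is.null(clustering))
    writeLines(clustering$newick,
               file.path(config$output_dir, "network_dendrogram.newick"))

  # ---- summary -------------------------------------------------------------
  node_counts <- vapply(nets, function(n) length(n$nodes), integer(1))
  edge_counts <- vapply(nets, function(n) nrow(n$edges), integer(1))
  size_cor <- if (length(nets) >= 3 && stats::sd(node_counts) > 0 &&
                  stats::sd(samples_per_sc) > 0)
    stats::cor(samples_per_sc[names(nets)], node_counts) else NA_real_
  summary <- list(
    seed = seed,
    subcontexts = names(nets),
    n_nodes = as.list(node_counts),
    n_edges = as.list(edge_counts),
    samples_per_subcontext = as.list(samples_per_sc),
    samples_vs_nodes_correlation = size_cor,
    interactome = list(n_nodes = igraph::gorder(interactome),
                       n_edges = igraph::gsize(interactome),
                       housekeeping_count = hk_overlap$count,
                       housekeeping_fraction = hk_overlap$fraction),
    controllability = list(n_driver = ctrl$n_driver,
                           node_percentages = as.list(ctrl$node_percentages)),
    fold_ratios = lapply(perms, `[[`, "fold_ratio"),
    edge_tiers = freq$tiers,
    fraction_unique_edges = freq$fraction_unique,
    n_in_all = length(commonality$in_all),
    n_in_exactly_one = length(commonality$in_exactly_one)
  )
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")

  bundle <- list(config = config, planted = planted, networks = nets,
                 merged = merged, interactome = interactome,
                 node_stats = stats_tab, housekeeping = housekeeping,
                 housekeeping_overlap = hk_overlap,
                 controllability = ctrl, overlap_matrix = ovl,
                 edge_frequency = freq, node_commonality = commonality,
                 permutation_tests = perms, common_most = common_most,
                 common_least = common_least, pathways = pathways,
                 pathway_similarity = simmat, clustering = clustering,
                 summary = summary)
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

# Draw interactome node ids from the gene universe, making sure planted
# module genes are represented (the interactome is smaller than the
# expression universe, as in real corpora).
sample_genes_for_interactome <- function(planted, n_nodes, seed) {
  set.seed(seed)
  module_g <- names(planted$module_assignments)[!is.na(planted$module_assignments)]
  background <- setdiff(planted$genes, module_g)
  if (n_nodes >= length(planted$genes)) return(planted$genes)
  take_mod <- min(length(module_g), n_nodes)
  c(module_g[seq_len(take_mod)],
    sample(background, n_nodes - take_mod))
}

# Read a corpus written by write_corpus() back into the simulate_expression()
# return shape (minus the ground truth).
load_corpus <- function(dir) {
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  probe_map <- utils::read.table(file.path(dir, "probe_map.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  ds_ids <- unique(meta$dataset_id)
  datasets <- lapply(ds_ids, function(ds) {
    list(values = read_expression_tsv(file.path(dir, paste0(ds, ".tsv"))),
         dataset_id = ds,
         subcontext = meta$subcontext[match(ds, meta$dataset_id)])
  })
  names(datasets) <- ds_ids
  list(datasets = datasets, metadata = meta, probe_map = probe_map)
}

#' Human-readable report of a pipeline bundle
#'
#' Tabulates the controllability summary, node/edge commonality counts,
#' edge-frequency tiers and permutation fold ratios as markdown lines.
#' Missing bundle components produce a named warning line instead of an
#' error.
#'
#' @param bundle Result of [run_pipeline()].
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
pipeline_report <- function(bundle) {
  out <- c("# contextnet pipeline report", "")
  warn <- function(what) paste0("*warning: missing artifact '", what, "'*")
  if (!is.null(bundle$summary)) {
    s <- bundle$summary
    out <- c(out, "## Networks", "",
             sprintf("- %s: %s nodes, %s edges",
                     s$subcontexts, unlist(s$n_nodes), unlist(s$n_edges)),
             sprintf("- samples-vs-nodes Pearson r: %s",
                     format(s$samples_vs_nodes_correlation, digits = 3)), "")
  } else out <- c(out, warn("summary"), "")
  if (!is.null(bundle$controllability)) {
    ctrl <- bundle$controllability
    out <- c(out, "## Interactome controllability", "",
             sprintf("- driver nodes (N_D): %d", ctrl$n_driver),
             sprintf("- %s: %d nodes (%.2f%%)", names(ctrl$node_counts),
                     ctrl$node_counts, ctrl$node_percentages), "")
  } else out <- c(out, warn("controllability"), "")
  if (!is.null(bundle$edge_frequency)) {
    tiers <- bundle$edge_frequency$tiers
    out <- c(out, "## Edge commonality", "",
             sprintf("- unique edges: %d (%.1f%%)",
                     bundle$edge_frequency$n_unique,
                     100 * bundle$edge_frequency$fraction_unique),
             sprintf("- >=%d%% of networks: %d edges (%.2f%%)",
                     round(100 * tiers$tier), tiers$n_edges,
                     100 * tiers$fraction), "")
  } else out <- c(out, warn("edge_frequency"), "")
  if (!is.null(bundle$node_commonality)) {
    out <- c(out, "## Node commonality", "",
             sprintf("- in all networks: %d", length(bundle$node_commonality$in_all)),
             sprintf("- in exactly one network: %d",
                     length(bundle$node_commonality$in_exactly_one)), "")
  } else out <- c(out, warn("node_commonality"), "")
  if (!is.null(bundle$permutation_tests)) {
    out <- c(out, "## Interactome overlap vs permuted networks", "",
             sprintf("- %s: observed %d, fold ratio %.3f, p = %.4g",
                     names(bundle$permutation_tests),
                     vapply(bundle$permutation_tests, `[[`, integer(1), "observed"),
                     vapply(bundle$permutation_tests, `[[`, numeric(1), "fold_ratio"),
                     vapply(bundle$permutation_tests, `[[`, numeric(1), "empirical_p")),
             "")
  } else out <- c(out, warn("permutation_tests"), "")
  cat(out, sep = "\n")
  invisible(out)
}
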