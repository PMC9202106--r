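#' Configuration for the synthetic expression corpus
#'
#' The generator emulates the statistical structure the downstream pipeline
#' assumes in a curated multi-dataset microarray corpus: several datasets
#' (batches) per biological subcontext, planted co-expression modules that are
#' either shared across all subcontexts or specific to one, per-batch additive
#' and multiplicative effects, and genes measured by one or more probes.
#'
#' Planted modules follow an equicorrelated single-factor model: for a gene
#' `g` in module `m` and sample `j`,
#' `x_gj = sqrt(r) * f_mj + sqrt(1 - r) * eps_gj`,
#' with `f` and `eps` standard normal, so any two genes of the same module
#' have latent correlation exactly `r = within_module_correlation`. Batch
#' effects then act gene-wise: `y = x * exp(s) + d + noise`, with
#' `d ~ N(0, batch_shift_sd^2)` and `s ~ N(0, batch_scale_sd^2)` drawn once
#' per (batch, gene) — the additive/multiplicative model that empirical-Bayes
#' batch correction assumes.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_subcontexts Number of biological subcontexts (e.g. tissues).
#' @param datasets_per_subcontext Datasets (= batches) per subcontext.
#' @param samples_per_dataset Samples per dataset; either a single count or
#'   a vector recycled over subcontexts (all datasets of one subcontext share
#'   a size). The default varies sizes across subcontexts the way curated
#'   corpora do, which keeps the sample-count-versus-network-size check
#'   meaningful.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module (modules are disjoint).
#' @param shared_module_fraction Fraction of modules active in every
#'   subcontext (these define the housekeeping ground truth); the remaining
#'   modules are assigned round-robin to single subcontexts.
#' @param within_module_correlation Latent pairwise correlation `r` of genes
#'   within an active module, in (0, 1).
#' @param batch_shift_sd SD of the additive per-(batch, gene) offset.
#' @param batch_scale_sd SD of the log multiplicative per-(batch, gene) factor.
#' @param probes_per_gene_max Maximum probes measuring one gene (each gene
#'   gets 1..max probes, fixed across datasets).
#' @param noise_sd SD of i.i.d. measurement noise added after batch effects.
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 1000,
                              n_subcontexts = 3,
                              datasets_per_subcontext = 3,
                              samples_per_dataset = c(14, 20, 26),
                              n_modules = 6,
                              module_size = 20,
                              shared_module_fraction = 1 / 3,
                              within_module_correlation = 0.8,
                              batch_shift_sd = 1,
                              batch_scale_sd = 0.1,
                              probes_per_gene_max = 2,
                              noise_sd = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_subcontexts = as.integer(n_subcontexts),
    datasets_per_subcontext = as.integer(datasets_per_subcontext),
    samples_per_dataset = as.integer(samples_per_dataset),  # may be a vector

    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    shared_module_fraction = shared_module_fraction,
    within_module_correlation = within_module_correlation,
    batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd,
    probes_per_gene_max = as.integer(probes_per_gene_max),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_subcontexts", "datasets_per_subcontext",
              "samples_per_dataset", "module_size", "probes_per_gene_max")
  for (f in counts) {
    if (anyNA(cfg[[f]]) || any(cfg[[f]] < 1L))
      stop2("invalid simulation_config: '", f, "' must be a count >= 1")
  }
  if (length(cfg$samples_per_dataset) > 1)
    cfg$samples_per_dataset <- rep_len(cfg$samples_per_dataset, cfg$n_subcontexts)
  if (cfg$n_modules < 0L)
    stop2("invalid simulation_config: 'n_modules' must be >= 0")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop2("invalid simulation_config: n_modules * module_size exceeds n_genes")
  if (cfg$within_module_correlation <= 0 || cfg$within_module_correlation >= 1)
    stop2("invalid simulation_config: 'within_module_correlation' must lie in (0, 1)")
  if (cfg$shared_module_fraction < 0 || cfg$shared_module_fraction > 1)
    stop2("invalid simulation_config: 'shared_module_fraction' must lie in [0, 1]")
  for (f in c("batch_shift_sd", "batch_scale_sd", "noise_sd")) {
    if (cfg[[f]] < 0)
      stop2("invalid simulation_config: '", f, "' must be non-negative")
  }
  structure(cfg, class = "simulation_config")
}

# Probe model constants: probe 1 carries the full gene signal with the least
# measurement noise; later probes carry an attenuated signal with more noise,
# so probe 1 is deterministically the most variable probe of its gene.
.PROBE_ATTENUATION <- 0.5
.probe_noise_sd <- function(k) 0.05 + 0.10 * (k - 1)

#' Simulate a multi-dataset probe-level expression corpus
#'
#' Generates `datasets_per_subcontext` probe-by-sample matrices for each
#' subcontext under the planted-module factor model described in
#' [simulation_config()], applies per-batch shift/scale effects and
#' measurement noise, expands genes into probes, and returns the ground
#' truth needed for parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{datasets}{named list; one element per dataset with `values`
#'       (probes x samples matrix), `dataset_id`, `subcontext`.}
#'     \item{metadata}{data.frame: `sample_id`, `dataset_id`, `subcontext`,
#'       `usable`, `is_reference`.}
#'     \item{probe_map}{data.frame: `probe_id`, `gene_id`.}
#'     \item{planted}{`planted_structure`: module assignments, per-subcontext
#'       active modules, batch parameters, housekeeping truth.}
#'   }
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(derive_seed(config$seed, "expression"))

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  modules <- if (config$n_modules > 0) sprintf("m%d", seq_len(config$n_modules)) else character()
  assignment <- rep(NA_character_, config$n_genes)
  names(assignment) <- genes
  if (config$n_modules > 0) {
    idx <- seq_len(config$n_modules * config$module_size)
    assignment[idx] <- rep(modules, each = config$module_size)
  }

  subcontexts <- sprintf("sc%d", seq_len(config$n_subcontexts))
  n_shared <- if (config$n_modules > 0) round(config$shared_module_fraction * config$n_modules) else 0L
  shared <- modules[seq_len(n_shared)]
  specific <- setdiff(modules, shared)
  subcontext_modules <- stats::setNames(vector("list", length(subcontexts)), subcontexts)
  for (i in seq_along(subcontexts)) subcontext_modules[[i]] <- shared
  for (j in seq_along(specific)) {
    sc <- subcontexts[((j - 1) %% length(subcontexts)) + 1]
    subcontext_modules[[sc]] <- c(subcontext_modules[[sc]], specific[j])
  }

  probes_per_gene <- sample.int(config$probes_per_gene_max, config$n_genes, replace = TRUE)
  names(probes_per_gene) <- genes
  probe_map <- data.frame(
    probe_id = unlist(lapply(genes, function(g)
      sprintf("%s_p%d", g, seq_len(probes_per_gene[[g]])))),
    gene_id = rep(genes, probes_per_gene),
    stringsAsFactors = FALSE
  )

  dataset_ids <- as.vector(vapply(subcontexts, function(sc)
    sprintf("%s_ds%d", sc, seq_len(config$datasets_per_subcontext)),
    character(config$datasets_per_subcontext)))
  batch_shift <- matrix(stats::rnorm(config$n_genes * length(dataset_ids),
                                     sd = config$batch_shift_sd),
                        nrow = config$n_genes,
                        dimnames = list(genes, dataset_ids))
  batch_logscale <- matrix(stats::rnorm(config$n_genes * length(dataset_ids),
                                        sd = config$batch_scale_sd),
                           nrow = config$n_genes,
                           dimnames = list(genes, dataset_ids))

  r <- config$within_module_correlation
  datasets <- list()
  meta <- list()
  sc_sizes <- rep_len(config$samples_per_dataset, length(subcontexts))
  for (si in seq_along(subcontexts)) {
    sc <- subcontexts[si]
    active <- subcontext_modules[[sc]]
    for (d in seq_len(config$datasets_per_subcontext)) {
      ds <- sprintf("%s_ds%d", sc, d)
      ns <- sc_sizes[si]
      sample_ids <- sprintf("%s_s%02d", ds, seq_len(ns))
      # latent gene-level signal
      x <- matrix(stats::rnorm(config$n_genes * ns), nrow = config$n_genes,
                  dimnames = list(genes, sample_ids))
      if (length(active) > 0) {
        factors <- matrix(stats::rnorm(length(active) * ns), nrow = length(active),
                          dimnames = list(active, NULL))
        for (m in active) {
          member <- genes[!is.na(assignment) & assignment == m]
          x[member, ] <- sqrt(r) * matrix(rep(factors[m, ], each = length(member)),
                                          nrow = length(member)) +
            sqrt(1 - r) * x[member, ]
        }
      }
      # batch effects + measurement noise at the gene level
      y <- x * exp(batch_logscale[, ds]) + batch_shift[, ds] +
        matrix(stats::rnorm(config$n_genes * ns, sd = config$noise_sd),
               nrow = config$n_genes)
      # expand genes into probes
      pvals <- matrix(NA_real_, nrow = nrow(probe_map), ncol = ns,
                      dimnames = list(probe_map$probe_id, sample_ids))
      for (k in seq_len(config$probes_per_gene_max)) {
        sel <- probe_map$probe_id[sub(".*_p", "", probe_map$probe_id) == as.character(k)]
        if (length(sel) == 0) next
        gsel <- probe_map$gene_id[match(sel, probe_map$probe_id)]
        att <- if (k == 1) 1 else .PROBE_ATTENUATION
        pvals[sel, ] <- att * y[gsel, , drop = FALSE] +
          matrix(stats::rnorm(length(sel) * ns, sd = .probe_noise_sd(k)),
                 nrow = length(sel))
      }
      datasets[[ds]] <- list(values = pvals, dataset_id = ds, subcontext = sc)
      meta[[ds]] <- data.frame(sample_id = sample_ids, dataset_id = ds,
                               subcontext = sc, usable = TRUE,
                               is_reference = TRUE, stringsAsFactors = FALSE)
    }
  }

  planted <- structure(list(
    module_assignments = assignment,
    subcontext_modules = subcontext_modules,
    shared_modules = shared,
    batch_shift = batch_shift,
    batch_logscale = batch_logscale,
    housekeeping_truth = sort(genes[!is.na(assignment) & assignment %in% shared]),
    probes_per_gene = probes_per_gene,
    genes = genes,
    config = config
  ), class = "planted_structure")

  list(datasets = datasets,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       probe_map = probe_map,
       planted = planted)
}

#' Genes of the same planted module
#'
#' @param planted A `planted_structure`.
#' @param module Module id (e.g. `"m1"`).
#' @return Character vector of member genes.
#' @export
module_genes <- function(planted, module) {
  a <- planted$module_assignments
  names(a)[!is.na(a) & a == module]
}

#' Simulate a directed scale-free interactome
#'
#' Grows a simple directed graph by preferential attachment (new nodes attach
#' to existing nodes with probability proportional to degree + 1, edge
#' direction random), then adds degree-biased edges until exactly `n_edges`
#' directed edges exist. No self-loops, no duplicate directed edges.
#'
#' Optionally, a fraction of the edges is drawn from pairs of genes belonging
#' to the same planted co-expression module, so that synthetic co-expression
#' networks share more edges with the interactome than degree-matched
#' permutations do — the contrast the permutation test is designed to detect.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of directed edges; must not exceed
#'   `n_nodes * (n_nodes - 1)`.
#' @param seed Integer seed.
#' @param node_ids Optional character vector of node names (length
#'   `n_nodes`); defaults to `p00001`, `p00002`, ...
#' @param planted Optional `planted_structure`; enables module-aligned edges.
#' @param planted_edge_fraction Fraction of edges drawn from same-module
#'   pairs when `planted` is given.
#' @return A directed `igraph` graph with exactly `n_nodes` nodes and
#'   `n_edges` edges.
#' @export
simulate_interactome <- function(n_nodes, n_edges, seed, node_ids = NULL,
                                 planted = NULL, planted_edge_fraction = 0.2) {
  n_nodes <- as.integer(n_nodes); n_edges <- as.integer(n_edges)
  if (n_nodes < 1) stop2("n_nodes must be >= 1")
  if (n_edges > n_nodes * (n_nodes - 1L))
    stop2("infeasible edge count: n_edges exceeds n_nodes * (n_nodes - 1)")
  if (is.null(node_ids)) node_ids <- sprintf("p%05d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes || anyDuplicated(node_ids))
    stop2("node_ids must be ", n_nodes, " unique names")
  set.seed(derive_seed(seed, "interactome"))

  deg <- integer(n_nodes)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  src <- integer(0); dst <- integer(0)
  add_edge <- function(a, b) {
    if (a == b) return(FALSE)
    key <- paste0(a, ">", b)
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    src <<- c(src, a); dst <<- c(dst, b)
    deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
    TRUE
  }

  # Per-node source propensity: U-shaped, so some proteins act mostly as
  # regulators (out-edges) and others mostly as targets (in-edges). This
  # heterogeneity is what gives real interactomes their unmatched nodes and
  # hence a non-trivial driver-node set.
  src_prop <- stats::rbeta(n_nodes, 0.5, 0.5)

  # number of module-aligned edges to reserve
  mods <- if (is.null(planted)) character() else
    unique(stats::na.omit(planted$module_assignments))
  want <- if (length(mods) > 0) round(planted_edge_fraction * n_edges) else 0L
  grow_target <- max(0L, n_edges - want)

  # preferential-attachment growth
  m <- max(1L, n_edges %/% max(1L, n_nodes))
  if (n_nodes >= 2) {
    for (i in 2:n_nodes) {
      for (k in seq_len(m)) {
        if (length(src) >= grow_target) break
        tgt <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)] + 1)
        if (stats::runif(1) < src_prop[i]) add_edge(i, tgt) else add_edge(tgt, i)
      }
    }
  }

  # module-aligned edges
  if (want > 0) {
    attempts <- 0L
    while (length(src) < n_edges && want > 0 && attempts < 50L * n_edges) {
      attempts <- attempts + 1L
      mgenes <- intersect(module_genes(planted, sample(mods, 1L)), node_ids)
      if (length(mgenes) < 2) next
      pair <- match(sample(mgenes, 2L), node_ids)
      if (add_edge(pair[1], pair[2])) want <- want - 1L
    }
  }

  # degree-biased fill to the exact edge count (sources by out-propensity,
  # targets by in-propensity, rich-get-richer on total degree)
  attempts <- 0L
  while (length(src) < n_edges) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_edges + 1000L) {
      # near-complete graphs: enumerate the missing arcs directly
      all_pairs <- expand.grid(a = seq_len(n_nodes), b = seq_len(n_nodes))
      all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
      have <- paste0(src, ">", dst)
      missing <- all_pairs[!paste0(all_pairs$a, ">", all_pairs$b) %in% have, ]
      need <- n_edges - length(src)
      take <- missing[sample.int(nrow(missing), need), ]
      for (i in seq_len(nrow(take))) add_edge(take$a[i], take$b[i])
      break
    }
    a <- sample.int(n_nodes, 1L, prob = (deg + 1) * src_prop)
    b <- sample.int(n_nodes, 1L, prob = (deg + 1) * (1 - src_prop))
    add_edge(a, b)
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = node_ids[src], to = node_ids[dst],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))
  stopifnot(igraph::gorder(g) == n_nodes, igraph::gsize(g) == n_edges)
  g
}

#' Simulate pathway gene sets
#'
#' A `planted_fraction` of the pathways is sampled from single planted
#' modules (these should score highly against networks where their module is
#' active); the remainder are uniform random gene sets, which at a 1% edge
#' density should score near zero.
#'
#' @param planted A `planted_structure`.
#' @param n_pathways Number of pathways to generate.
#' @param pathway_size_range Integer pair `(min, max)` of member counts;
#'   both at least 2.
#' @param planted_fraction Fraction of pathways drawn from planted modules.
#' @param seed Integer seed.
#' @return A list of `pathway_gene_set` objects (`id`, `name`, `members`).
#' @export
simulate_pathways <- function(planted, n_pathways,
                              pathway_size_range = c(5L, 15L),
                              planted_fraction = 0.5, seed = 1L) {
  n_pathways <- as.integer(n_pathways)
  lo <- as.integer(pathway_size_range[1]); hi <- as.integer(pathway_size_range[2])
  if (lo < 2L || hi < lo) stop2("pathway sizes must be >= 2 with min <= max")
  universe <- planted$genes
  if (hi > length(universe)) stop2("pathway size exceeds the gene universe")
  if (n_pathways == 0L) return(list())
  set.seed(derive_seed(seed, "pathways"))

  mods <- unique(stats::na.omit(planted$module_assignments))
  n_planted <- if (length(mods) > 0) round(planted_fraction * n_pathways) else 0L
  out <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    size <- sample(lo:hi, 1L)
    if (i <= n_planted) {
      m <- sample(mods, 1L)
      pool <- module_genes(planted, m)
      members <- sort(sample(pool, min(size, length(pool))))
      src <- paste0("module:", m)
    } else {
      members <- sort(sample(universe, size))
      src <- "random"
    }
    out[[i]] <- structure(list(id = sprintf("PW%03d", i),
                               name = sprintf("pathway %03d (%s)", i, src),
                               members = members),
                          class = "pathway_gene_set")
  }
  out
}

#' Housekeeping ground truth from the planted structure
#'
#' Housekeeping genes are defined as members of modules active in every
#' subcontext (the shared modules): their co-expression is context-invariant
#' by construction. Returns an empty vector when no module is shared.
#'
#' @param planted A `planted_structure`.
#' @return Sorted character vector of gene ids.
#' @export
simulate_housekeeping <- function(planted) {
  planted$housekeeping_truth
}

# ---- plain-text writers / readers for the corpus formats -------------------

#' Write / read an expression matrix as TSV
#'
#' First column `probe_id` (or `gene_id`), remaining columns one per sample.
#'
#' @param values Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_expression_tsv` returns the numeric matrix.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(probe_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write the synthetic corpus to a directory
#'
#' Emits the plain-text exchange formats consumed by the pipeline: one
#' expression TSV per dataset, a sample metadata TSV, a probe-to-gene map
#' TSV, and a ground-truth JSON.
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in names(sim$datasets))
    write_expression_tsv(sim$datasets[[ds]]$values,
                         file.path(dir, paste0(ds, ".tsv")))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$probe_map, file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    module_assignments = as.list(sim$planted$module_assignments[
      !is.na(sim$planted$module_assignments)]),
    subcontext_modules = sim$planted$subcontext_modules,
    shared_modules = sim$planted$shared_modules,
    housekeeping_truth = sim$planted$housekeeping_truth
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a housekeeping gene list (one gene per line)
#'
#' @param genes Character vector of gene ids.
#' @param path File path.
#' @return `read_housekeeping` returns the character vector.
#' @export
write_housekeeping <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_housekeeping
#' @export
read_housekeeping <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
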