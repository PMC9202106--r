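test_that("simulation_config validates its invariants by name", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(n_genes = 50, n_modules = 6, module_size = 10),
               "exceeds n_genes")
  expect_error(simulation_config(within_module_correlation = 1),
               "within_module_correlation")
  expect_error(simulation_config(batch_shift_sd = -1), "batch_shift_sd")
})

test_that("generator is deterministic under a fixed seed, including on disk", {
  a <- simulate_expression(small_sim_config(seed = 5))
  b <- simulate_expression(small_sim_config(seed = 5))
  expect_identical(a$datasets, b$datasets)
  expect_identical(a$planted, b$planted)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(a, d1); write_corpus(b, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  c2 <- simulate_expression(small_sim_config(seed = 6))
  expect_false(identical(a$datasets, c2$datasets))
})

test_that("corpus has the configured shape and metadata", {
  cfg <- small_sim_config(seed = 2)
  sim <- simulate_expression(cfg)
  expect_length(sim$datasets, cfg$n_subcontexts * cfg$datasets_per_subcontext)
  expect_setequal(unique(sim$metadata$subcontext), c("sc1", "sc2", "sc3"))
  for (ds in sim$datasets) {
    expect_equal(ncol(ds$values), 10)
    expect_true(all(rownames(ds$values) %in% sim$probe_map$probe_id))
  }
  # every gene has between 1 and probes_per_gene_max probes
  per_gene <- table(sim$probe_map$gene_id)
  expect_true(all(per_gene >= 1 & per_gene <= cfg$probes_per_gene_max))
  # shared module genes are the housekeeping truth and appear in every
  # subcontext's active set
  for (sc in names(sim$planted$subcontext_modules))
    expect_true(all(sim$planted$shared_modules %in%
                      sim$planted$subcontext_modules[[sc]]))
})

test_that("module structure is absent when n_modules = 0", {
  cfg <- simulation_config(n_genes = 60, n_subcontexts = 1,
                           datasets_per_subcontext = 1,
                           samples_per_dataset = 50, n_modules = 0,
                           batch_shift_sd = 0, batch_scale_sd = 0,
                           probes_per_gene_max = 1, seed = 3)
  sim <- simulate_expression(cfg)
  cc <- cor(t(sim$datasets[[1]]$values))
  off <- cc[upper.tri(cc)]
  expect_lt(abs(mean(off)), 0.05)
  expect_length(simulate_housekeeping(sim$planted), 0)
})

test_that("same-module genes reach the configured correlation (Monte Carlo)", {
  # factor model without batch effects, 10 x 20 = 200 pooled samples;
  # measurement noise attenuates r = 0.8 to ~ 0.8 / (1 + noise var)
  rs <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 50, n_subcontexts = 1,
                             datasets_per_subcontext = 10,
                             samples_per_dataset = 20, n_modules = 1,
                             module_size = 10, shared_module_fraction = 1,
                             within_module_correlation = 0.8,
                             batch_shift_sd = 0, batch_scale_sd = 0,
                             probes_per_gene_max = 1, seed = s)
    sim <- simulate_expression(cfg)
    pooled <- do.call(cbind, lapply(sim$datasets, `[[`, "values"))
    g <- paste0(module_genes(sim$planted, "m1"), "_p1")
    cor(pooled[g[1], ], pooled[g[2], ])
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
  expect_lt(mean(rs), 0.9)
})

test_that("probe 1 is the most variable probe of its gene", {
  cfg <- simulation_config(n_genes = 100, n_subcontexts = 1,
                           datasets_per_subcontext = 1,
                           samples_per_dataset = 60, n_modules = 2,
                           module_size = 10, probes_per_gene_max = 3, seed = 8)
  sim <- simulate_expression(cfg)
  v <- apply(sim$datasets[[1]]$values, 1, var)
  multi <- names(which(table(sim$probe_map$gene_id) > 1))
  wins <- vapply(multi, function(g) {
    probes <- sim$probe_map$probe_id[sim$probe_map$gene_id == g]
    names(which.max(v[probes])) == paste0(g, "_p1")
  }, logical(1))
  expect_true(all(wins))
})

test_that("simulated interactome honours its count contracts and is simple", {
  g <- simulate_interactome(8601 %/% 20, 199535 %/% 20, seed = 1)
  expect_equal(igraph::gorder(g), 430)
  expect_equal(igraph::gsize(g), 9976)
  expect_true(igraph::is_simple(g))
  expect_equal(sum(igraph::which_loop(g)), 0)
  # heavy-tailed degrees: max far above median
  deg <- igraph::degree(g)
  expect_gt(max(deg), 5 * median(deg))
  # forced complete case
  g2 <- simulate_interactome(2, 2, seed = 1)
  el <- igraph::as_edgelist(g2, names = FALSE)
  expect_setequal(paste(el[, 1], el[, 2]), c("1 2", "2 1"))
  expect_error(simulate_interactome(3, 7, seed = 1), "infeasible")
})

test_that("pathway generator separates planted from random sets", {
  sim <- simulate_expression(small_sim_config(seed = 4))
  expect_length(simulate_pathways(sim$planted, 0, seed = 1), 0)
  # planted_fraction = 0: no pathway concentrates in a single module
  for (s in 1:5) {
    pws <- simulate_pathways(sim$planted, 10, planted_fraction = 0, seed = s)
    mods <- unique(na.omit(sim$planted$module_assignments))
    for (p in pws) {
      frac_in_mod <- vapply(mods, function(m)
        mean(p$members %in% module_genes(sim$planted, m)), numeric(1))
      expect_lt(max(frac_in_mod), 0.5)
    }
  }
  expect_error(simulate_pathways(sim$planted, 5, pathway_size_range = c(2, 1e4),
                                 seed = 1), "universe")
  expect_error(simulate_pathways(sim$planted, 5, pathway_size_range = c(1, 5),
                                 seed = 1), ">= 2")
})

test_that("housekeeping truth is exactly the genes of shared modules", {
  sim <- simulate_expression(small_sim_config(seed = 9))
  hk <- simulate_housekeeping(sim$planted)
  shared <- sim$planted$shared_modules
  expect_setequal(hk, unlist(lapply(shared, module_genes,
                                    planted = sim$planted)))
  expect_true(all(hk %in% sim$planted$genes))
  # one shared module of size 10 here
  expect_length(hk, 10)
})

test_that("batch effects dominate before correction and vanish after", {
  skip_if_not_installed("cluster")
  cfg <- simulation_config(n_genes = 200, n_subcontexts = 1,
                           datasets_per_subcontext = 2,
                           samples_per_dataset = 20, n_modules = 2,
                           module_size = 10, shared_module_fraction = 1,
                           batch_shift_sd = 3, batch_scale_sd = 0.05,
                           noise_sd = 0.3, probes_per_gene_max = 1, seed = 3)
  sim <- simulate_expression(cfg)
  merged <- merge_by_subcontext(lapply(sim$datasets, function(d)
    collapse_probes(d$values, sim$probe_map)), "sc1")
  sil <- function(ge) {
    pc <- prcomp(t(ge$values), rank. = 2)$x
    mean(cluster::silhouette(as.integer(factor(ge$batch)), dist(pc))[, 3])
  }
  expect_gt(sil(merged), 0.5)
  expect_lt(sil(combat_adjust(merged)), 0.1)
})
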