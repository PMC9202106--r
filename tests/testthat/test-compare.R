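test_that("pairwise_edge_overlap is exact set intersection", {
  a <- toy_network(list(c("A", "B"), c("B", "C"), c("C", "D")))
  b <- toy_network(list(c("B", "C"), c("D", "E")))
  expect_equal(pairwise_edge_overlap(a, b), 1)
  expect_equal(pairwise_edge_overlap(a, a), 3)
  disjoint <- toy_network(list(c("X", "Y")))
  expect_equal(pairwise_edge_overlap(a, disjoint), 0)
  # brute-force oracle on random subsets of a toy universe
  for (s in 1:5) {
    n1 <- rand_network(15, 30, seed = s)
    n2 <- rand_network(15, 30, seed = 100 + s)
    k1 <- paste(n1$edges$gene_a, n1$edges$gene_b)
    k2 <- paste(n2$edges$gene_a, n2$edges$gene_b)
    expect_equal(pairwise_edge_overlap(n1, n2), sum(k1 %in% k2))
  }
  # overlap matrix symmetry, diagonal = edge count
  m <- overlap_matrix(list(a = a, b = b))
  expect_equal(m["a", "a"], 3L)
  expect_equal(m["a", "b"], m["b", "a"])
})

test_that("edge_frequency tiers count commonality over the edge union", {
  a <- toy_network(list(c("A", "B"), c("B", "C")))
  ident <- edge_frequency(list(a, a))
  expect_equal(ident$n_unique, 0)
  expect_true(all(ident$table$count == 2))
  b <- toy_network(list(c("X", "Y"), c("Y", "Z")))
  disj <- edge_frequency(list(a, b))
  expect_equal(disj$n_unique, 4)
  expect_equal(disj$fraction_unique, 1)
  # planted common edge among 4 networks: alone in the >= 75% tier
  common <- c("M", "N")
  nets4 <- lapply(1:4, function(i)
    toy_network(list(common, c(paste0("u", i), paste0("v", i)))))
  freq4 <- edge_frequency(nets4)
  t75 <- freq4$tiers[freq4$tiers$tier == 0.75, ]
  expect_equal(t75$n_edges, 1)
  expect_equal(freq4$table$count[freq4$table$gene_a == "M"], 4L)
  # tier monotonicity
  expect_true(all(diff(freq4$tiers$n_edges) <= 0))
})

test_that("node_commonality splits genes by membership count", {
  a <- toy_network(list(c("A", "B"), c("B", "C")))
  expect_equal(node_commonality(list(a, a)),
               list(in_all = c("A", "B", "C"), in_exactly_one = character(0)))
  b <- toy_network(list(c("X", "Y")))
  nc <- node_commonality(list(a, b))
  expect_equal(nc$in_all, character(0))
  expect_setequal(nc$in_exactly_one, c("A", "B", "C", "X", "Y"))
  # hand-counted fixture
  c1 <- toy_network(list(c("A", "B")))
  c2 <- toy_network(list(c("A", "C")))
  c3 <- toy_network(list(c("A", "B"), c("C", "D")))
  nc3 <- node_commonality(list(c1, c2, c3))
  expect_equal(nc3$in_all, "A")
  expect_equal(nc3$in_exactly_one, "D")
})

test_that("interactome_edge_overlap ignores direction", {
  g <- igraph::graph_from_literal(B -+ A, C -+ B, D -+ E)
  net <- toy_network(list(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_equal(interactome_edge_overlap(net, g), 2)
  sub <- toy_network(list(c("A", "B")))
  expect_equal(interactome_edge_overlap(sub, g), 1)
  none <- toy_network(list(c("P", "Q")))
  expect_equal(interactome_edge_overlap(none, g), 0)
})

test_that("xswap preserves the degree multiset on 100 random networks", {
  for (s in 1:100) {
    set.seed(s)
    net <- rand_network(sample(10:25, 1), sample(12:40, 1), seed = s)
    perm <- suppressWarnings(xswap(net, seed = s))
    d0 <- table(c(net$edges$gene_a, net$edges$gene_b))
    d1 <- table(c(perm$edges$gene_a, perm$edges$gene_b))
    expect_identical(sort(names(d0)), sort(names(d1)))
    expect_equal(as.integer(d1[names(d0)]), as.integer(d0))
    expect_equal(nrow(perm$edges), nrow(net$edges))
  }
})

test_that("a swap-locked triangle returns unchanged with a warning", {
  tri <- toy_network(list(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_warning(out <- xswap(tri, seed = 1), "identical")
  expect_setequal(paste(out$edges$gene_a, out$edges$gene_b),
                  paste(tri$edges$gene_a, tri$edges$gene_b))
})

test_that("xswap mixes: large networks move far from their input", {
  net <- rand_network(40, 100, seed = 77)
  k0 <- paste(net$edges$gene_a, net$edges$gene_b)
  for (s in 1:3) {
    perm <- xswap(net, n_swap_multiplier = 10, seed = s)
    k1 <- paste(perm$edges$gene_a, perm$edges$gene_b)
    jac <- length(intersect(k0, k1)) / length(union(k0, k1))
    expect_lt(jac, 0.5)
  }
})

test_that("permutation test is calibrated on a permuted network", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:150)
  net <- rand_network(150, 1000, seed = 1)
  g <- simulate_interactome(150, 5000, seed = 9, node_ids = genes)
  netp <- xswap(net, seed = 77)  # a 'null' network drawn from the null
  pt <- permutation_overlap_test(netp, g, n_perm = 200, seed = 101)
  expect_gt(pt$fold_ratio, 0.9)
  expect_lt(pt$fold_ratio, 1.1)
  expect_length(pt$permuted, 200)
  expect_true(pt$empirical_p > 0 && pt$empirical_p <= 1)
})

test_that("permutation test flags enrichment of a planted clique", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:60)
  clique <- utils::combn(genes[1:12], 2)
  filler <- rand_network(60, 80, seed = 3)
  keys_cl <- paste(clique[1, ], clique[2, ])
  keys_f <- paste(filler$edges$gene_a, filler$edges$gene_b)
  extra <- filler$edges[!keys_f %in% keys_cl, ][1:40, ]
  net <- build_network(rbind(
    data.frame(gene_a = clique[1, ], gene_b = clique[2, ], weight = 1),
    extra), "clique")
  # interactome containing every clique pair plus random arcs
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = clique[1, ], to = clique[2, ]),
          data.frame(from = sample(genes, 150, TRUE),
                     to = sample(genes, 150, TRUE))), directed = TRUE)
  g <- igraph::simplify(g)
  pt <- permutation_overlap_test(net, g, n_perm = 200, seed = 5)
  expect_gt(pt$fold_ratio, 1)
  expect_lte(pt$empirical_p, 0.05)
})

test_that("degenerate interactome gives observed 0 with flagged ratio 0", {
  net <- toy_network(list(c("A", "B"), c("A", "C"), c("B", "D")))
  g <- igraph::graph_from_literal(x -+ y, y -+ z)
  pt <- permutation_overlap_test(net, g, n_perm = 5, seed = 3)
  expect_equal(pt$observed, 0)
  expect_equal(pt$fold_ratio, 0)
  expect_true(pt$degenerate)
  # determinism at n_perm = 1
  p1 <- permutation_overlap_test(net, g, n_perm = 1, seed = 11)
  p2 <- permutation_overlap_test(net, g, n_perm = 1, seed = 11)
  expect_identical(p1$permuted, p2$permuted)
})

test_that("common-protein overlap matches a hand-built ranking fixture", {
  # gene membership counts: A,B in 3 networks; C in 2; D,E in 1
  nets <- list(
    toy_network(list(c("A", "B"), c("C", "D"))),
    toy_network(list(c("A", "B"), c("C", "E"))),
    toy_network(list(c("A", "B")))
  )
  g <- igraph::graph_from_literal(A -+ B, A -+ C, A -+ D, B -+ C, X -+ A)
  # degrees: A=5, B=2? (A->B, B->C) => B:2, C:2, D:1, X:1
  most <- common_protein_degree_overlap(nets, g, k = 2, end = "most")
  expect_equal(most$gene, c("A", "B"))
  expect_true(all(most$n_networks == 3))
  least <- common_protein_degree_overlap(nets, g, k = 2, end = "least",
                                         housekeeping = "D")
  expect_equal(least$gene, "D")
  expect_true(least$housekeeping)
  # k larger than the universe truncates with a warning
  expect_warning(all_g <- common_protein_degree_overlap(nets, g, k = 100,
                                                        end = "most"),
                 "truncat")
  expect_setequal(all_g$gene, intersect(c("A", "B", "C", "D", "E"),
                                        igraph::V(g)$name))
})
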