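test_that("network generator is deterministic, seed-sensitive and hits its mean degree", {
  spec <- network_spec(1000, 8, seed = 7)
  g1 <- generate_network(spec)
  g2 <- generate_network(spec)
  expect_identical(edge_key_set(g1), edge_key_set(g2))
  expect_identical(igraph::E(g1)$weight, igraph::E(g2)$weight)

  g3 <- generate_network(network_spec(1000, 8, seed = 8))
  expect_false(identical(edge_key_set(g1), edge_key_set(g3)))

  md <- 2 * igraph::ecount(g1) / igraph::vcount(g1)
  expect_lt(abs(md - 8) / 8, 0.10)
  expect_true(igraph::is_simple(g1))
  expect_true(all(igraph::E(g1)$weight >= 0.5 & igraph::E(g1)$weight <= 1))
  expect_match(igraph::V(g1)$name[1], "^SYN\\d{5}$")
})

test_that("saturated Erdos-Renyi density yields the complete graph", {
  g <- generate_network(network_spec(4, 3, "erdos_renyi", seed = 1))
  expect_equal(igraph::ecount(g), 6)
  expect_true(all(igraph::degree(g) == 3))
})

test_that("infeasible configuration-model degree sequences are rejected with a diagnostic", {
  expect_error(
    generate_network(network_spec(4, 2.9, "configuration_poisson", seed = 1)),
    "infeasible degree sequence.*n_nodes=4.*mean_degree=2.9")
})

test_that("spec constructors validate their invariants", {
  expect_error(network_spec(3, 1), "n_nodes")
  expect_error(network_spec(10, 9.5), "mean_degree")
  expect_error(network_spec(10, 11), "mean_degree")
  expect_error(network_spec(10, 3, weight_range = c(0.9, 0.2)), "weight_range")
  expect_error(crosstalk_spec(10, 10, n_core_A = 11), "n_core_A")
  expect_error(expression_sim_spec(c(NON_DEG = 10), effect_log2fc = 0.5))
})

test_that("planted crosstalk matches the closed-form cross-edge expectation", {
  net <- generate_network(network_spec(2000, 8, seed = 11))
  res <- plant_crosstalk(net, crosstalk_spec(50, 200, enrichment_factor = 5,
                                             seed = 12))
  man <- res$manifest
  # realized cross-edge count ~ 5 x the background expectation |A||B|p
  expect_lt(abs(man$realized_cross_total / (5 * man$expected_background_cross) - 1),
            0.15)
  # per-gene manifest counts recompute exactly by brute force
  recount <- vapply(c(man$set_A[1:5], man$set_B[1:5]), function(g) {
    opp <- if (g %in% man$set_A) man$set_B else man$set_A
    brute_cross_count(res$network, g, opp)
  }, integer(1))
  expect_identical(unname(recount),
                   unname(man$realized_cross_per_gene[names(recount)]))
  expect_equal(man$realized_cross_total,
               brute_global_cross(res$network, man$set_A, man$set_B))
})

test_that("null planting (factor 1, no cores) returns the input graph unchanged", {
  net <- generate_network(network_spec(500, 8, seed = 3))
  res <- plant_crosstalk(net, crosstalk_spec(30, 60, enrichment_factor = 1,
                                             seed = 4))
  expect_identical(edge_key_set(res$network), edge_key_set(net))
  expect_equal(res$manifest$n_cross_added, 0)
})

test_that("core-gene bookkeeping is exact", {
  net <- generate_network(network_spec(800, 10, seed = 5))
  res <- plant_crosstalk(net, crosstalk_spec(40, 100, enrichment_factor = 3,
                                             n_core_A = 5, n_core_B = 7, seed = 6))
  expect_length(res$manifest$core_A, 5)
  expect_length(res$manifest$core_B, 7)
  expect_true(all(res$manifest$core_A %in% res$manifest$set_A))
  expect_true(all(res$manifest$core_B %in% res$manifest$set_B))
  expect_true(igraph::is_simple(res$network))
})

test_that("contrast tables round-trip through the classifier at zero noise", {
  counts <- c(ABA_DEPENDENT = 10, ABA_INDEPENDENT = 40,
              NOT_RECOVERED = 10, NON_DEG = 140)
  sim <- generate_contrast_table(expression_sim_spec(counts, seed = 21))
  cls <- classify_degs(sim$table)
  expect_identical(as.integer(table(cls$class)[names(counts)]),
                   as.integer(unname(counts)))
  expect_identical(as.character(cls$class),
                   unname(sim$manifest$classes[cls$gene_id]))
})

test_that("an all-NON_DEG table produces no DEG calls in any contrast", {
  sim <- generate_contrast_table(expression_sim_spec(c(NON_DEG = 80), seed = 2))
  for (ct in c("drought10", "drought12", "rewater2", "aba4"))
    expect_length(call_contrast_degs(sim$table, ct), 0)
})

test_that("contrast-table generation is byte-identical on rerun", {
  spec <- expression_sim_spec(c(ABA_DEPENDENT = 5, NON_DEG = 20), seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_contrast_table(generate_contrast_table(spec)$table, f1)
  write_contrast_table(generate_contrast_table(spec)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("label noise corrupts roughly the stated fraction of genes", {
  spec <- expression_sim_spec(c(ABA_DEPENDENT = 150, NON_DEG = 150),
                              label_noise = 0.2, seed = 31)
  sim <- generate_contrast_table(spec)
  frac <- length(sim$manifest$noisy_genes) / 300
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("expression matrix has planted dimensions and correlation structure", {
  counts <- c(ABA_DEPENDENT = 30, ABA_INDEPENDENT = 30, NON_DEG = 40)
  spec <- expression_sim_spec(counts, seed = 41)
  m <- generate_expression_matrix(spec, 200, within_class_cor = 0.9,
                                  between_deg_cor = 0)
  expect_identical(dim(m), c(100L, 200L))
  expect_true(all(m > 0))
  lx <- log(m)
  C <- cor(t(lx))
  a <- 1:30; b <- 31:60
  within_a <- mean(C[a, a][upper.tri(C[a, a])])
  between <- mean(C[a, b])
  expect_gt(within_a, between)
  expect_gt(within_a, 0.7)
  expect_lt(abs(between), 0.15)

  # zero planted correlation -> near-zero mean absolute correlation
  m0 <- generate_expression_matrix(expression_sim_spec(counts, seed = 42), 150,
                                   within_class_cor = 0, between_deg_cor = 0)
  C0 <- cor(t(log(m0)))
  expect_lt(mean(abs(C0[upper.tri(C0)])), 3 / sqrt(150))
})

test_that("simulate_study wires planted sets into table classes and manifest", {
  st <- simulate_study(n_nodes = 400, mean_degree = 12, size_A = 20,
                       size_B = 50, enrichment_factor = 4, n_core_A = 3,
                       n_core_B = 5, n_not_recovered = 15, n_samples = 10,
                       seed = 77)
  cls <- classify_degs(st$contrast_table)
  got_A <- sort(cls$gene_id[cls$class == "ABA_DEPENDENT"])
  expect_identical(got_A, st$sets$A)
  got_B <- sort(cls$gene_id[cls$class == "ABA_INDEPENDENT"])
  expect_identical(got_B, st$sets$B)
  expect_identical(sort(cls$gene_id[cls$class == "NOT_RECOVERED"]),
                   st$sets$not_recovered)
  expect_identical(dim(st$expression),
                   c(as.integer(igraph::vcount(st$network)), 10L))
})
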