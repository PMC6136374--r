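test_that("cross_edge_count matches brute-force enumeration on the toy graph", {
  g <- toy_graph(rbind(c("a1", "b1"), c("a1", "b2"), c("a2", "a3"),
                       c("b1", "b3")), isolated = "a9")
  expect_equal(cross_edge_count(g, "a1", c("b1", "b2", "b3")), 2)
  expect_equal(cross_edge_count(g, "a1", character(0)), 0)
  expect_equal(cross_edge_count(g, "a9", c("b1", "b2")), 0)  # no edges
  expect_error(cross_edge_count(g, "zz", "b1"), "not in network")
})

test_that("observed and null cross-counts equal brute force on small random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:14, 1)
    g <- igraph::sample_gnm(n, sample(5:min(30, n * (n - 1) / 2), 1))
    igraph::V(g)$name <- sprintf("G%02d", seq_len(n))
    nodes <- igraph::V(g)$name
    A <- sample(nodes, 3)
    B <- sample(setdiff(nodes, A), 4)
    ens <- build_ensemble(g, R = 3, seed = seed + 100)
    rec <- per_gene_enrichment(g, ens, A, B)
    for (k in seq_len(nrow(rec))) {
      opp <- if (rec$set[k] == "A") B else A
      expect_equal(rec$observed_cross[k], brute_cross_count(g, rec$gene_id[k], opp))
    }
    nulls <- attr(rec, "null_counts")
    for (i in 1:3) {
      gi <- ensemble_replicate(ens, i)
      for (k in seq_len(nrow(rec))) {
        opp <- if (rec$set[k] == "A") B else A
        expect_equal(nulls[k, i], brute_cross_count(gi, rec$gene_id[k], opp))
      }
    }
    glob <- global_enrichment(g, ens, A, B)
    expect_equal(glob$n_observed, brute_global_cross(g, A, B))
    # symmetry: swapping the sets leaves the global count unchanged
    expect_equal(global_enrichment(g, ens, B, A)$n_observed, glob$n_observed)
  }
})

test_that("empirical p is the tie-inclusive proportion of the null at or above observed", {
  # craft a network and replicates with exactly known null counts for a1:
  # observed 2 cross edges; nulls 0, 1, 1, 2, 5 -> p = 2/5
  net <- toy_graph(rbind(c("a1", "b1"), c("a1", "b2"), c("a1", "c1"),
                         c("a2", "c2"), c("a2", "c3")),
                   isolated = c("b3", "b4", "b5", "c4", "c5"))
  nodes <- igraph::V(net)$name
  idx <- function(x) match(x, nodes)
  mk <- function(...) {
    pr <- list(...)
    m <- do.call(rbind, lapply(pr, function(p) c(idx(p[1]), idx(p[2]))))
    storage.mode(m) <- "integer"
    m
  }
  reps <- list(
    mk(c("a1", "c1"), c("a1", "c2"), c("a1", "c3"), c("a2", "c4"), c("a2", "c5")),  # 0
    mk(c("a1", "b1"), c("a1", "c1"), c("a1", "c2"), c("a2", "c3"), c("a2", "c4")),  # 1
    mk(c("a1", "b2"), c("a1", "c1"), c("a1", "c2"), c("a2", "c3"), c("a2", "c4")),  # 1
    mk(c("a1", "b1"), c("a1", "b2"), c("a1", "c1"), c("a2", "c2"), c("a2", "c3")),  # 2
    mk(c("a1", "b1"), c("a1", "b2"), c("a1", "b3"), c("a1", "b4"), c("a1", "b5")))  # 5
  ens <- fake_ensemble(net, reps)
  rec <- per_gene_enrichment(net, ens, c("a1", "a2"), c("b1", "b2", "b3", "b4", "b5"))
  a1 <- rec[rec$gene_id == "a1", ]
  expect_equal(a1$observed_cross, 2)
  expect_identical(attr(rec, "null_counts")[1, ], c(0L, 1L, 1L, 2L, 5L))
  expect_equal(a1$empirical_p, 0.4)
  # a2 has no cross edges: every null count >= 0 -> p = 1
  expect_equal(rec[rec$gene_id == "a2", "empirical_p"], 1)
  expect_equal(attr(rec, "min_p"), 1 / 5)
  # pseudocount variant shifts to (r+1)/(R+1)
  recp <- per_gene_enrichment(net, ens, c("a1", "a2"), paste0("b", 1:5),
                              pseudocount = TRUE)
  expect_equal(recp[recp$gene_id == "a1", "empirical_p"], 3 / 6)
})

test_that("observed above every null reports p = 0 with a resolvable floor", {
  net <- toy_graph(rbind(c("a1", "b1"), c("a1", "b2"), c("x1", "x2")))
  el <- igraph::as_edgelist(net, names = FALSE); storage.mode(el) <- "integer"
  swap <- matrix(match(c("a1", "x1", "x2", "b1", "x1", "b2"),
                       igraph::V(net)$name), ncol = 2, byrow = TRUE)
  storage.mode(swap) <- "integer"
  ens <- fake_ensemble(net, list(swap, swap, swap, swap))
  rec <- per_gene_enrichment(net, ens, "a1", c("b1", "b2"))
  expect_equal(rec$empirical_p[rec$gene_id == "a1"], 0)
  expect_equal(attr(rec, "min_p"), 0.25)
})

test_that("set handling: overlap errors, absent genes are unscorable", {
  g <- toy_graph(rbind(c("a1", "b1"), c("a2", "b2")))
  ens <- build_ensemble(g, R = 2, seed = 1)
  expect_error(per_gene_enrichment(g, ens, c("a1", "b1"), c("b1", "b2")),
               "disjoint")
  expect_message(rec <- per_gene_enrichment(g, ens, c("a1", "GHOST"), c("b1", "b2")),
                 "absent from the network")
  expect_identical(attr(rec, "unscored"), "GHOST")
  expect_false("GHOST" %in% rec$gene_id)
  h <- toy_graph(rbind(c("a1", "b1"), c("a2", "b2"), c("a3", "b3")))
  expect_error(per_gene_enrichment(h, ens, "a1", "b1"), "not built from")
})

test_that("global Z-score follows (observed - null mean) / null sd", {
  A <- paste0("a", 1:5); B <- paste0("b", 1:5)
  full_pairs <- as.matrix(expand.grid(A, B, stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE))
  filler_pool <- rbind(cbind("u1", c(A, B)), cbind("u2", A))
  # observed network: 10 cross edges + 5 filler edges (15 edges total)
  net <- toy_graph(rbind(full_pairs[1:10, ], filler_pool[1:5, ]),
                   isolated = c("u2", setdiff(B, full_pairs[1:10, 2])))
  nodes <- igraph::V(net)$name
  cross_rep <- function(k) {
    m <- rbind(full_pairs[seq_len(k), , drop = FALSE],
               filler_pool[seq_len(15 - k), , drop = FALSE])
    m <- cbind(match(m[, 1], nodes), match(m[, 2], nodes))
    storage.mode(m) <- "integer"
    m
  }
  # nulls 2, 4, 6: mu = 4, sd = 2; observed 10 -> z = (10 - 4)/2 = 3
  ens <- fake_ensemble(net, list(cross_rep(2), cross_rep(4), cross_rep(6)))
  glob <- global_enrichment(net, ens, A, B)
  expect_equal(glob$n_observed, 10)
  expect_equal(glob$mu_null, 4)
  expect_equal(glob$sd_null, 2)
  expect_equal(glob$z_score, 3)
  # observed equal to the null mean -> z = 0
  ens0 <- fake_ensemble(net, list(cross_rep(8), cross_rep(10), cross_rep(12)))
  expect_equal(global_enrichment(net, ens0, A, B)$z_score, 0)
  # degenerate null: identical replicates -> flagged, no division by zero
  same <- fake_ensemble(net, list(cross_rep(4), cross_rep(4)))
  g0 <- global_enrichment(net, same, A, B)
  expect_true(g0$degenerate)
  expect_true(is.na(g0$z_score))
})

test_that("core selection thresholds the empirical p and the subnetwork is induced", {
  rec <- data.frame(gene_id = c("a1", "a2", "b1", "b2"),
                    set = c("A", "A", "B", "B"),
                    empirical_p = c(0.01, 1, 0.04, 0.2))
  cores <- select_core_components(rec, alpha = 0.05)
  expect_identical(cores$core_A, "a1")
  expect_identical(cores$core_B, "b1")
  expect_identical(select_core_components(rec, alpha = 1)$core_B, c("b1", "b2"))
  all1 <- transform(rec, empirical_p = 1)
  expect_length(select_core_components(all1)$core_A, 0)

  g <- toy_graph(rbind(c("a1", "b1"), c("a1", "x"), c("b1", "b2")))
  sub <- extract_core_subnetwork(g, "a1", c("b1", "b2"), rec)
  expect_identical(edge_key_set(sub), c("a1 b1", "b1 b2"))
  expect_equal(sub$n_cross_edges, 1)
  expect_equal(sub$n_within_edges, 1)
  expect_identical(igraph::V(sub)$set[igraph::V(sub)$name == "a1"], "A")
  empty <- extract_core_subnetwork(g, character(0), character(0))
  expect_equal(igraph::vcount(empty), 0)
})

test_that("adding a cross edge cannot increase any empirical p on a fixed null", {
  net <- generate_network(network_spec(100, 6, seed = 50))
  nodes <- igraph::V(net)$name
  A <- nodes[1:10]; B <- nodes[11:30]
  ens <- build_ensemble(net, R = 50, seed = 51)
  rec <- per_gene_enrichment(net, ens, A, B)
  nulls <- attr(rec, "null_counts")
  for (k in seq_len(nrow(rec))) {
    p_now <- rec$empirical_p[k]
    p_plus <- mean(nulls[k, ] >= rec$observed_cross[k] + 1)
    expect_lte(p_plus, p_now)
  }
})

test_that("compare_zscores at full subsample reproduces the global Z and validates the pool", {
  st <- simulate_study(n_nodes = 300, mean_degree = 10, size_A = 15,
                       size_B = 40, enrichment_factor = 3, n_samples = 0,
                       n_not_recovered = 5, seed = 61)
  ens <- build_ensemble(st$network, R = 40, seed = 62)
  glob <- global_enrichment(st$network, ens, st$sets$A, st$sets$B)
  zc <- compare_zscores(st$network, ens, st$sets$A, st$sets$B, st$sets$pool,
                        n_resamples = 1, subsample_fraction = 1, seed = 63)
  expect_equal(zc$z_deg, glob$z_score, tolerance = 1e-10)
  expect_error(
    compare_zscores(st$network, ens, st$sets$A, st$sets$B, st$sets$pool[1:10]),
    "too small")
  expect_error(
    compare_zscores(st$network, ens, st$sets$A, st$sets$B,
                    c(st$sets$A[1], st$sets$pool)), "overlap")
})

test_that("planted interaction enrichment separates DEG pairs from non-DEG pairs", {
  st <- simulate_study(n_nodes = 500, mean_degree = 16, size_A = 25,
                       size_B = 60, enrichment_factor = 5, n_samples = 0,
                       n_not_recovered = 10, seed = 71)
  ens <- build_ensemble(st$network, R = 100, seed = 72)
  zc <- compare_zscores(st$network, ens, st$sets$A, st$sets$B, st$sets$pool,
                        n_resamples = 25, seed = 73)
  expect_gt(mean(zc$z_deg), mean(zc$z_nondeg))
  expect_lt(zc$p_value, 0.05)
})

test_that("coexpression links: trivial full-fraction case and planted signal", {
  counts <- c(ABA_DEPENDENT = 25, ABA_INDEPENDENT = 40, NON_DEG = 160)
  spec <- expression_sim_spec(counts, seed = 81)
  ids <- syn_gene_ids(225)
  cls <- rep(names(counts), counts)
  A <- ids[cls == "ABA_DEPENDENT"]; B <- ids[cls == "ABA_INDEPENDENT"]
  pool <- ids[cls == "NON_DEG"]

  # strong shared factor between A and B, absent from the pool
  m <- generate_expression_matrix(spec, 60, within_class_cor = 0.6,
                                  between_deg_cor = 0.5)
  cx <- coexpression_enrichment(m, A, B, pool, n_resamples = 20, seed = 82)
  expect_gt(cx$fold_enrichment, 1.5)

  # top_fraction 1: every pair is a link, enrichment 1 by construction
  cx1 <- coexpression_enrichment(m, A, B, pool, top_fraction = 1,
                                 n_resamples = 5, seed = 83)
  expect_equal(cx1$n_links_observed, length(A) * length(B))
  expect_equal(cx1$fold_enrichment, 1)
})

test_that("coexpression fold is near 1 when no correlation is planted", {
  counts <- c(ABA_DEPENDENT = 40, ABA_INDEPENDENT = 80, NON_DEG = 250)
  m <- generate_expression_matrix(expression_sim_spec(counts, seed = 91), 100,
                                  within_class_cor = 0, between_deg_cor = 0)
  ids <- rownames(m)
  cls <- rep(names(counts), counts)
  cx <- coexpression_enrichment(m, ids[cls == "ABA_DEPENDENT"],
                                ids[cls == "ABA_INDEPENDENT"],
                                ids[cls == "NON_DEG"],
                                n_resamples = 40, seed = 92)
  expect_gt(cx$fold_enrichment, 0.5)
  expect_lt(cx$fold_enrichment, 1.7)
})

test_that("zero-variance genes are dropped with a warning", {
  m <- generate_expression_matrix(expression_sim_spec(
    c(ABA_DEPENDENT = 10, ABA_INDEPENDENT = 10, NON_DEG = 40), seed = 95), 20)
  m[3, ] <- 7  # constant gene in set A
  ids <- rownames(m)
  expect_warning(
    cx <- coexpression_enrichment(m, ids[1:10], ids[11:20], ids[21:50],
                                  n_resamples = 5, seed = 96),
    "zero-variance")
  expect_s3_class(cx, "coexpression_enrichment")
})
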