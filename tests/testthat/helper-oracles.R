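# Independent oracles used across tests: everything here is deliberately
# naive (edge-by-edge loops, closed forms, exhaustive enumeration) and stays
# independent of the package's counting code paths.

# named undirected graph from a 2-column character matrix of endpoints
toy_graph <- function(pairs, isolated = character(0)) {
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# brute-force cross-set neighbor count for one gene: loop over every edge
brute_cross_count <- function(net, gene, opposing) {
  el <- igraph::as_edgelist(net)
  cnt <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    other <- if (a == gene) b else if (b == gene) a else next
    if (other %in% opposing && !other %in% seen) {
      cnt <- cnt + 1L
      seen <- c(seen, other)
    }
  }
  cnt
}

# brute-force distinct A-B edge count
brute_global_cross <- function(net, A, B) {
  el <- igraph::as_edgelist(net)
  sum((el[, 1] %in% A & el[, 2] %in% B) | (el[, 1] %in% B & el[, 2] %in% A))
}

# Pearson r from the textbook formula, no stats:: shortcuts
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# canonical sorted edge-key set of a graph, for exact edge-set comparison
edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# exhaustively enumerate all simple labeled graphs on n nodes with the given
# degree sequence and edge count m (feasible only for tiny n)
enumerate_degseq_graphs <- function(n, degs, m) {
  all_pairs <- t(combn(n, 2))
  subsets <- combn(nrow(all_pairs), m)
  keep <- list()
  for (k in seq_len(ncol(subsets))) {
    rows <- all_pairs[subsets[, k], , drop = FALSE]
    if (all(tabulate(as.vector(rows), n) == degs)) {
      keep[[length(keep) + 1]] <-
        sort(paste(rows[, 1], rows[, 2]))
    }
  }
  keep
}

# a fabricated ensemble with hand-chosen replicate edge matrices, for tests
# that need exactly known null counts (bypasses the swap chain on purpose)
fake_ensemble <- function(net, replicate_edge_lists) {
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  structure(list(node_names = igraph::V(net)$name,
                 n_nodes = igraph::vcount(net),
                 source_edges = el,
                 replicates = lapply(replicate_edge_lists, function(x) {
                   storage.mode(x) <- "integer"; x
                 }),
                 R = length(replicate_edge_lists),
                 swap_multiplier = NA, master_seed = NA,
                 replicate_seeds = rep(NA_integer_, length(replicate_edge_lists)),
                 acceptance_rate = NA_real_),
            class = "random_ensemble")
}
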