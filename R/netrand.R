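#' Degree-preserving edge shuffle of a simple network
#'
#' Randomizes a simple undirected network by the double-edge-swap Markov
#' chain: `swap_multiplier * ecount(net)` attempts, each picking two edges
#' uniformly at random and re-pairing their endpoints (one of the two
#' pairings, chosen at random), rejecting any swap that would create a
#' self-loop or parallel edge. Every node keeps its degree exactly. Edge
#' weights travel with their edge slot, i.e. a rewired edge keeps the weight
#' of the first parent edge occupying that slot; weights do not enter any
#' downstream count statistic.
#'
#' @param net A simple undirected `igraph`.
#' @param swap_multiplier Attempted swaps per edge (default 10).
#' @param seed Optional integer seed.
#' @return A shuffled `igraph` with the same vertex set and degree sequence.
#'   Graph attributes `swap_attempts` and `swap_accepted` record the realized
#'   acceptance of the chain.
#' @examples
#' g <- igraph::sample_gnp(50, 0.2)
#' h <- degree_preserving_shuffle(g, seed = 1)
#' all(igraph::degree(h) == igraph::degree(g))
#' @export
degree_preserving_shuffle <- function(net, swap_multiplier = 10, seed = NULL) {
  stopifnot(igraph::is_igraph(net), !igraph::is_directed(net),
            igraph::is_simple(net), swap_multiplier >= 1)
  m <- igraph::ecount(net)
  if (m < 2) {
    warning("fewer than 2 edges; returning an identical copy (no swap possible)")
    return(net)
  }
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  res <- double_edge_swap_cpp(el, igraph::vcount(net), as.integer(round(swap_multiplier * m)))
  out <- igraph::delete_edges(net, igraph::E(net))
  out <- igraph::add_edges(out, as.vector(t(res$edges)))
  if (!is.null(igraph::E(net)$weight))
    igraph::E(out)$weight <- igraph::E(net)$weight
  out$swap_attempts <- res$attempts
  out$swap_accepted <- res$accepted
  out
}

#' Build a degree-preserving randomized-network ensemble
#'
#' Generates `R` independent shuffles of `net` (each a fresh double-edge-swap
#' run from the source network), the null model for all interaction
#' enrichment statistics. Per-replicate seeds are drawn deterministically
#' from the master seed, so the ensemble is reproducible as a whole and any
#' single replicate can be regenerated in isolation.
#'
#' @inheritParams degree_preserving_shuffle
#' @param R Number of randomized networks (default 1000).
#' @param seed Master seed (default 1).
#' @return An object of class `random_ensemble` storing the source edge
#'   list, per-replicate edge lists (vertex indices), seeds, and the mean
#'   swap acceptance rate.
#' @export
build_ensemble <- function(net, R = 1000, swap_multiplier = 10, seed = 1L) {
  stopifnot(igraph::is_igraph(net), R >= 1)
  m <- igraph::ecount(net)
  if (m < 2) stop("network must have at least 2 edges")
  set.seed(seed)
  rep_seeds <- sample.int(.max_seed, R)
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  n <- igraph::vcount(net)
  attempts <- as.integer(round(swap_multiplier * m))
  accepted <- integer(R)
  replicates <- vector("list", R)
  for (i in seq_len(R)) {
    set.seed(rep_seeds[i])
    res <- double_edge_swap_cpp(el, n, attempts)
    replicates[[i]] <- res$edges
    accepted[i] <- res$accepted
  }
  structure(list(node_names = igraph::V(net)$name, n_nodes = n,
                 source_edges = el, replicates = replicates, R = R,
                 swap_multiplier = swap_multiplier, master_seed = seed,
                 replicate_seeds = rep_seeds,
                 acceptance_rate = mean(accepted) / attempts),
            class = "random_ensemble")
}

#' @method print random_ensemble
#' @export
print.random_ensemble <- function(x, ...) {
  cat("Degree-preserving random ensemble\n",
      "  source: ", x$n_nodes, " nodes, ", nrow(x$source_edges), " edges\n",
      "  replicates: ", x$R, " (swap multiplier ", x$swap_multiplier,
      ", mean acceptance ", signif(x$acceptance_rate, 3), ")\n",
      "  master seed: ", x$master_seed, "\n", sep = "")
  invisible(x)
}

#' Materialize one ensemble replicate as an igraph
#'
#' @param ensemble A [build_ensemble()] result.
#' @param i Replicate index.
#' @return An `igraph` with the source's vertex names.
#' @export
ensemble_replicate <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "random_ensemble"), i >= 1, i <= ensemble$R)
  g <- igraph::make_empty_graph(ensemble$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(ensemble$replicates[[i]])))
  if (!is.null(ensemble$node_names)) igraph::V(g)$name <- ensemble$node_names
  g
}

# sparse adjacency of one replicate (or any 2-col index matrix)
.rep_adjacency <- function(edges, n) {
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = 1, dims = c(n, n))
}
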