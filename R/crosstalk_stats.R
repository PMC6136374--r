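# cross-set edge counting on an edge-index matrix; inA/inB are logical
# membership vectors over vertex indices. Sets must be disjoint, so no edge
# is counted from both orientations.
.cross_count_vectors <- function(edges, inA, inB, n) {
  a1 <- inA[edges[, 1]]; a2 <- inA[edges[, 2]]
  b1 <- inB[edges[, 1]]; b2 <- inB[edges[, 2]]
  r1 <- a1 & b2; r2 <- a2 & b1
  list(countA = tabulate(c(edges[r1, 1], edges[r2, 2]), n),
       countB = tabulate(c(edges[r1, 2], edges[r2, 1]), n),
       total = sum(r1) + sum(r2))
}

.check_ensemble_matches <- function(net, ensemble) {
  stopifnot(inherits(ensemble, "random_ensemble"))
  if (igraph::vcount(net) != ensemble$n_nodes ||
      igraph::ecount(net) != nrow(ensemble$source_edges) ||
      !identical(igraph::V(net)$name, ensemble$node_names))
    stop("ensemble was not built from this network")
}

#' Count a gene's interactions with an opposing gene set
#'
#' Number of distinct network neighbors of `gene` that belong to
#' `opposing_set` (unweighted: an interaction either exists or not).
#'
#' @param net An `igraph` network with named vertices.
#' @param gene A gene id present in the network.
#' @param opposing_set Character vector of gene ids.
#' @return Integer count.
#' @export
cross_edge_count <- function(net, gene, opposing_set) {
  if (!gene %in% igraph::V(net)$name)
    stop("gene '", gene, "' not in network (unscorable)")
  nb <- igraph::neighbors(net, gene)$name
  sum(unique(nb) %in% opposing_set)
}

#' Per-gene cross-set interaction enrichment
#'
#' For every gene of set A, counts its interactions with the whole of set B
#' in the observed network and in each randomized replicate (and
#' symmetrically for genes of B versus A). The empirical p-value is the
#' proportion of null replicates whose count is greater than or equal to the
#' observed count; ties count toward the numerator, so the smallest
#' resolvable nonzero p is `1/R` (reported as attribute `min_p`). Genes
#' absent from the network are unscorable and reported via attribute
#' `unscored` with a message.
#'
#' @param net An `igraph` with named vertices.
#' @param ensemble A [build_ensemble()] result built from `net`.
#' @param set_A,set_B Disjoint character vectors of gene ids
#'   (A = ABA-dependent, B = ABA-independent).
#' @param pseudocount If `TRUE`, use the `(r + 1)/(R + 1)` estimator instead
#'   of the plain proportion (which can return exactly 0). Default `FALSE`.
#' @return A data.frame with one row per scorable gene: `gene_id`, `set`
#'   (`"A"` or `"B"`), `degree`, `observed_cross`, `null_mean`, `null_sd`,
#'   `empirical_p`, `bh_q` (Benjamini-Hochberg adjusted, informational only).
#'   Attributes: `null_counts` (gene x replicate matrix), `min_p`,
#'   `unscored`.
#' @export
per_gene_enrichment <- function(net, ensemble, set_A, set_B,
                                pseudocount = FALSE) {
  .check_ensemble_matches(net, ensemble)
  if (length(intersect(set_A, set_B)))
    stop("set_A and set_B overlap; the classes are disjoint by construction")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  unscored <- setdiff(c(set_A, set_B), nodes)
  if (length(unscored))
    message(length(unscored), " gene(s) absent from the network excluded from scoring")
  A <- intersect(set_A, nodes); B <- intersect(set_B, nodes)
  if (!length(A) || !length(B)) stop("no scorable genes in one of the sets")
  inA <- inB <- logical(n)
  idxA <- match(A, nodes); idxB <- match(B, nodes)
  inA[idxA] <- TRUE; inB[idxB] <- TRUE

  el <- igraph::as_edgelist(net, names = FALSE)
  obs <- .cross_count_vectors(el, inA, inB, n)
  observed <- c(obs$countA[idxA], obs$countB[idxB])

  R <- ensemble$R
  null_counts <- matrix(0L, length(A) + length(B), R)
  for (i in seq_len(R)) {
    cc <- .cross_count_vectors(ensemble$replicates[[i]], inA, inB, n)
    null_counts[, i] <- c(cc$countA[idxA], cc$countB[idxB])
  }
  ge <- null_counts >= observed
  emp_p <- if (pseudocount) (rowSums(ge) + 1) / (R + 1) else rowMeans(ge)

  res <- data.frame(
    gene_id = c(A, B),
    set = rep(c("A", "B"), c(length(A), length(B))),
    degree = igraph::degree(net)[c(idxA, idxB)],
    observed_cross = observed,
    null_mean = rowMeans(null_counts),
    null_sd = apply(null_counts, 1, sd),
    empirical_p = emp_p,
    bh_q = p.adjust(emp_p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "null_counts") <- null_counts
  attr(res, "min_p") <- 1 / R
  attr(res, "unscored") <- unscored
  res
}

#' Select core interacting components
#'
#' Genes whose cross-set interaction count is significant against the
#' randomized-network null (empirical p < `alpha`), split by source set.
#'
#' @param records Result of [per_gene_enrichment()].
#' @param alpha Significance threshold on the raw empirical p (default 0.05;
#'   no multiple-testing correction, matching the selection rule on raw
#'   empirical p-values).
#' @return A list with character vectors `core_A` and `core_B`.
#' @export
select_core_components <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "set", "empirical_p") %in% names(records)))
  sel <- records$empirical_p < alpha
  list(core_A = records$gene_id[sel & records$set == "A"],
       core_B = records$gene_id[sel & records$set == "B"])
}

#' Global cross-set interaction enrichment Z-score
#'
#' Counts the distinct A-B interactions in the observed network
#' (`n_observed`) and in each randomized replicate, and summarizes enrichment
#' as `z = (n_observed - mu_null) / sd_null`, where `mu_null` and `sd_null`
#' are the ensemble mean and sample standard deviation (denominator R - 1).
#' Each cross edge is counted once, so the count is symmetric in A and B.
#'
#' @inheritParams per_gene_enrichment
#' @return An object of class `global_enrichment`: `n_observed`, `mu_null`,
#'   `sd_null`, `z_score` (`NA` with `degenerate = TRUE` when `sd_null` is
#'   0), and the vector of `null_counts`.
#' @export
global_enrichment <- function(net, ensemble, set_A, set_B) {
  .check_ensemble_matches(net, ensemble)
  if (length(intersect(set_A, set_B))) stop("set_A and set_B overlap")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  inA <- nodes %in% set_A
  inB <- nodes %in% set_B
  el <- igraph::as_edgelist(net, names = FALSE)
  n_obs <- .cross_count_vectors(el, inA, inB, n)$total
  null_counts <- vapply(ensemble$replicates, function(e)
    .cross_count_vectors(e, inA, inB, n)$total, numeric(1))
  mu <- mean(null_counts)
  sdev <- sd(null_counts)
  z <- if (sdev > 0) (n_obs - mu) / sdev else NA_real_
  structure(list(n_observed = n_obs, mu_null = mu, sd_null = sdev,
                 z_score = z, degenerate = !(sdev > 0),
                 null_counts = null_counts, R = ensemble$R),
            class = "global_enrichment")
}

#' @method print global_enrichment
#' @export
print.global_enrichment <- function(x, ...) {
  cat("Global cross-set interaction enrichment\n",
      "  observed: ", x$n_observed, "  null mean: ", signif(x$mu_null, 5),
      "  null sd: ", signif(x$sd_null, 5), "\n",
      "  Z-score: ", if (x$degenerate) "undefined (sd_null = 0)"
      else signif(x$z_score, 5), "  (R = ", x$R, ")\n", sep = "")
  invisible(x)
}

# batch cross-set counts: Amat/Bmat are n x P indicator matrices of set
# pairs; returns per-pair counts for one edge set via the sparse adjacency.
# With disjoint pairs each A-B edge contributes exactly once.
.pair_cross_counts <- function(adj, Amat, Bmat) {
  Matrix::colSums(Amat * (adj %*% Bmat))
}

# z-scores for P set pairs against an ensemble
.pair_zscores <- function(net_adj, ensemble, Amat, Bmat) {
  P <- ncol(Amat)
  obs <- .pair_cross_counts(net_adj, Amat, Bmat)
  nulls <- matrix(0, P, ensemble$R)
  for (i in seq_len(ensemble$R)) {
    adj <- .rep_adjacency(ensemble$replicates[[i]], ensemble$n_nodes)
    nulls[, i] <- .pair_cross_counts(adj, Amat, Bmat)
  }
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1, sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  list(z = z, obs = obs, mu = mu, sd = sdev)
}

.indicator_matrix <- function(sets, nodes) {
  M <- matrix(0, length(nodes), length(sets))
  for (j in seq_along(sets)) M[match(sets[[j]], nodes), j] <- 1
  M
}

#' Compare DEG-pair Z-scores with size-matched non-DEG pairs
#'
#' Quantifies whether the two drought-responsive sets interact more than
#' random gene sets of the same size: draws `n_resamples` size-matched set
#' pairs from the non-DEG pool and computes each pair's cross-interaction
#' Z-score against the ensemble; the DEG side is turned into a distribution
#' by subsampling each set at `subsample_fraction` `n_resamples` times. The
#' two Z-score samples are compared with Welch's two-sample t-test.
#'
#' Note the DEG-side subsamples share most of their genes, so they are
#' anchored on the one realized DEG-pair Z-score and are not independent
#' draws; the t-test is descriptive rather than a calibrated test (see the
#' methods vignette).
#'
#' @inheritParams per_gene_enrichment
#' @param nondeg_pool Character vector of non-DEG gene ids, disjoint from
#'   `set_A` and `set_B`.
#' @param n_resamples Number of resampled pairs per side (default 100).
#' @param subsample_fraction Fraction of each DEG set kept per subsample
#'   (default 0.8). With `n_resamples = 1` and fraction 1 the DEG side is the
#'   single full-pair Z-score.
#' @param seed Optional integer seed.
#' @return An object of class `zscore_comparison`: `z_deg`, `z_nondeg`,
#'   `t_statistic`, `p_value`, `n_resamples`, `subsample_fraction`.
#' @export
compare_zscores <- function(net, ensemble, set_A, set_B, nondeg_pool,
                            n_resamples = 100, subsample_fraction = 0.8,
                            seed = NULL) {
  .check_ensemble_matches(net, ensemble)
  stopifnot(n_resamples >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  nodes <- igraph::V(net)$name
  A <- intersect(set_A, nodes); B <- intersect(set_B, nodes)
  pool <- intersect(nondeg_pool, nodes)
  if (length(intersect(pool, c(A, B))))
    stop("nondeg_pool overlaps the DEG sets")
  need <- length(A) + length(B)
  if (length(pool) < need)
    stop("nondeg_pool too small: need ", need, " genes per size-matched pair, have ",
         length(pool))
  if (!is.null(seed)) set.seed(seed)

  kA <- max(1, round(subsample_fraction * length(A)))
  kB <- max(1, round(subsample_fraction * length(B)))
  deg_pairs <- lapply(seq_len(n_resamples), function(i)
    list(a = if (kA == length(A)) A else sample(A, kA),
         b = if (kB == length(B)) B else sample(B, kB)))
  nd_pairs <- lapply(seq_len(n_resamples), function(i) {
    pick <- sample(pool, need)
    list(a = pick[seq_along(A)], b = pick[length(A) + seq_along(B)])
  })

  Amat <- .indicator_matrix(c(lapply(deg_pairs, `[[`, "a"),
                              lapply(nd_pairs, `[[`, "a")), nodes)
  Bmat <- .indicator_matrix(c(lapply(deg_pairs, `[[`, "b"),
                              lapply(nd_pairs, `[[`, "b")), nodes)
  el <- igraph::as_edgelist(net, names = FALSE)
  net_adj <- .rep_adjacency(el, length(nodes))
  zs <- .pair_zscores(net_adj, ensemble, Amat, Bmat)
  z_deg <- zs$z[seq_len(n_resamples)]
  z_nondeg <- zs$z[n_resamples + seq_len(n_resamples)]

  tt <- if (n_resamples >= 2) t.test(z_deg, z_nondeg) else
    list(statistic = NA_real_, p.value = NA_real_)
  structure(list(z_deg = z_deg, z_nondeg = z_nondeg,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 n_resamples = n_resamples,
                 subsample_fraction = subsample_fraction),
            class = "zscore_comparison")
}

#' @method print zscore_comparison
#' @export
print.zscore_comparison <- function(x, ...) {
  cat("Z-score comparison (DEG pairs vs size-matched non-DEG pairs)\n",
      "  mean Z (DEG): ", signif(mean(x$z_deg), 4),
      "   mean Z (non-DEG): ", signif(mean(x$z_nondeg), 4), "\n",
      "  Welch t = ", signif(x$t_statistic, 4),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Co-expression link enrichment between two gene sets
#'
#' Computes Pearson correlations (on log2-transformed abundances) over all
#' unordered pairs among set A, set B and `n_resamples` size-matched non-DEG
#' set pairs, takes the `1 - top_fraction` quantile of that pooled pair
#' correlation distribution as the link threshold (default: top 1% most
#' correlated pairs), and reports the number of A-B links at or above the
#' threshold and its fold enrichment over the mean link count among the
#' non-DEG pairs.
#'
#' @param expr Numeric matrix, genes x samples, gene ids as rownames
#'   (>= 3 samples).
#' @param set_A,set_B,nondeg_pool Character vectors of gene ids present in
#'   `expr`.
#' @param top_fraction Fraction of most-correlated pairs considered linked
#'   (default 0.01).
#' @param n_resamples Non-DEG set pairs for the baseline (default 50).
#' @param seed Optional integer seed.
#' @param log_transform Apply `log2(x + 1)` before correlating (default
#'   `TRUE`).
#' @return An object of class `coexpression_enrichment`:
#'   `correlation_threshold`, `n_links_observed`, `fold_enrichment`,
#'   `null_links`, `n_nondeg_resamples`, `top_fraction`. When no non-DEG
#'   pair reaches the threshold the fold enrichment is `Inf` (observed links
#'   over a zero baseline).
#' @export
coexpression_enrichment <- function(expr, set_A, set_B, nondeg_pool,
                                    top_fraction = 0.01, n_resamples = 50,
                                    seed = NULL, log_transform = TRUE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, !is.null(rownames(expr)),
            top_fraction > 0, top_fraction <= 1, n_resamples >= 1)
  genes <- rownames(expr)
  missing <- setdiff(c(set_A, set_B, nondeg_pool), genes)
  if (length(missing))
    stop(length(missing), " gene(s) absent from the expression matrix, e.g. ",
         missing[1])
  if (!is.null(seed)) set.seed(seed)
  x <- if (log_transform) log2(expr + 1) else expr
  zero_var <- apply(x, 1, sd) == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) dropped")
    x <- x[!zero_var, , drop = FALSE]
    set_A <- intersect(set_A, rownames(x))
    set_B <- intersect(set_B, rownames(x))
    nondeg_pool <- intersect(nondeg_pool, rownames(x))
  }
  need <- length(set_A) + length(set_B)
  if (length(nondeg_pool) < need)
    stop("nondeg_pool too small: need ", need, ", have ", length(nondeg_pool))
  nd_pairs <- lapply(seq_len(n_resamples), function(i) {
    pick <- sample(nondeg_pool, need)
    list(a = pick[seq_along(set_A)], b = pick[length(set_A) + seq_along(set_B)])
  })
  involved <- unique(c(set_A, set_B, unlist(lapply(nd_pairs, unlist))))
  C <- cor(t(x[involved, , drop = FALSE]))
  thr <- unname(quantile(C[upper.tri(C)], 1 - top_fraction))
  n_links <- sum(C[set_A, set_B, drop = FALSE] >= thr)
  null_links <- vapply(nd_pairs, function(p)
    sum(C[p$a, p$b, drop = FALSE] >= thr), numeric(1))
  structure(list(correlation_threshold = thr, n_links_observed = n_links,
                 fold_enrichment = n_links / mean(null_links),
                 null_links = null_links, n_nondeg_resamples = n_resamples,
                 top_fraction = top_fraction),
            class = "coexpression_enrichment")
}

#' @method print coexpression_enrichment
#' @export
print.coexpression_enrichment <- function(x, ...) {
  cat("Co-expression link enrichment (top ", x$top_fraction * 100,
      "% correlated pairs)\n",
      "  threshold r >= ", signif(x$correlation_threshold, 4),
      "; observed A-B links: ", x$n_links_observed, "\n",
      "  fold enrichment vs non-DEG pairs: ",
      signif(x$fold_enrichment, 4), "\n", sep = "")
  invisible(x)
}

#' Extract the core interacting subnetwork
#'
#' Induced subgraph on the core genes of both sets, annotated for Cytoscape
#' export: vertex attributes `set` (`"A"`/`"B"`) and `empirical_p` (when
#' `records` given); per-edge `weight` and `verified` attributes are carried
#' through from the input network. Graph attributes `n_cross_edges` and
#' `n_within_edges` give the split between edges connecting the two sets and
#' edges inside one core set.
#'
#' @param net An `igraph` with named vertices.
#' @param core_A,core_B Core gene ids (e.g. from [select_core_components()]).
#' @param records Optional [per_gene_enrichment()] result for annotation.
#' @return An `igraph` subnetwork.
#' @export
extract_core_subnetwork <- function(net, core_A, core_B, records = NULL) {
  keep <- intersect(c(core_A, core_B), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  igraph::V(sub)$set <- ifelse(igraph::V(sub)$name %in% core_A, "A", "B")
  if (!is.null(records)) {
    idx <- match(igraph::V(sub)$name, records$gene_id)
    igraph::V(sub)$empirical_p <- records$empirical_p[idx]
  }
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub)
    cross <- (el[, 1] %in% core_A) != (el[, 2] %in% core_A)
    sub$n_cross_edges <- sum(cross)
    sub$n_within_edges <- sum(!cross)
  } else {
    sub$n_cross_edges <- 0L
    sub$n_within_edges <- 0L
  }
  sub
}
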