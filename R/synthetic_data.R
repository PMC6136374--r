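#' Specification of a synthetic interaction network
#'
#' Describes a random PPI-like network at reduced scale. The default model is
#' a Poisson-degree configuration model, which mimics a predicted
#' genome-scale interactome (many nodes of moderate degree, simple graph,
#' per-edge confidence weights) without its heavy tail; `erdos_renyi` and
#' `powerlaw` variants are available for sensitivity checks.
#'
#' @param n_nodes Number of genes (>= 4).
#' @param mean_degree Target mean degree; must be < `n_nodes - 1`.
#' @param model One of `"configuration_poisson"`, `"erdos_renyi"`,
#'   `"powerlaw"`.
#' @param weight_range Length-2 numeric in (0, 1]: range of the uniform
#'   per-edge confidence weight (interaction probability).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `network_spec`.
#' @seealso [generate_network()]
#' @export
network_spec <- function(n_nodes, mean_degree,
                         model = c("configuration_poisson", "erdos_renyi", "powerlaw"),
                         weight_range = c(0.5, 1), seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 4,
            is.numeric(mean_degree), length(mean_degree) == 1, mean_degree > 0)
  if (mean_degree > n_nodes - 1)
    stop("mean_degree (", mean_degree, ") must be <= n_nodes - 1 (", n_nodes - 1, ")")
  stopifnot(length(weight_range) == 2, all(weight_range > 0), all(weight_range <= 1))
  if (weight_range[1] > weight_range[2]) stop("weight_range low must be <= high")
  structure(list(n_nodes = as.integer(n_nodes), mean_degree = mean_degree,
                 model = model, weight_range = weight_range, seed = as.integer(seed)),
            class = "network_spec")
}

#' Synthetic gene identifiers
#'
#' Zero-padded AGI-like labels (`SYN00001`, ...) so real AGI-keyed inputs are
#' drop-in compatible with synthetic fixtures.
#' @param n Number of identifiers.
#' @return Character vector of length `n`.
#' @export
syn_gene_ids <- function(n) sprintf("SYN%05d", seq_len(n))

#' Generate a synthetic interaction network
#'
#' Draws a simple undirected graph from the model in `spec`, labels nodes
#' with synthetic gene identifiers and attaches uniform confidence weights.
#' Identical spec (including seed) gives an identical graph.
#'
#' @param spec A [network_spec()].
#' @return An `igraph` object with `name` vertex attribute and `weight`
#'   edge attribute.
#' @examples
#' net <- generate_network(network_spec(100, 6, seed = 1))
#' igraph::vcount(net)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  g <- switch(spec$model,
    erdos_renyi = igraph::sample_gnp(n, min(1, spec$mean_degree / (n - 1))),
    configuration_poisson = {
      degs <- rpois(n, spec$mean_degree)
      if (sum(degs) %% 2 == 1) degs[which.min(degs)] <- degs[which.min(degs)] + 1L
      if (max(degs) >= n)
        stop("infeasible degree sequence: max sampled degree ", max(degs),
             " >= n_nodes ", n, " (n_nodes=", n, ", mean_degree=", spec$mean_degree, ")")
      if (!igraph::is_graphical(degs))
        stop("infeasible degree sequence for configuration model ",
             "(n_nodes=", n, ", mean_degree=", spec$mean_degree, ")")
      igraph::sample_degseq(degs, method = "fast.heur.simple")
    },
    powerlaw = igraph::sample_fitness_pl(n, round(n * spec$mean_degree / 2),
                                         exponent.out = 2.5))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- syn_gene_ids(n)
  igraph::E(g)$weight <- runif(igraph::ecount(g), spec$weight_range[1], spec$weight_range[2])
  g
}

#' Specification of planted cross-set crosstalk
#'
#' Defines the alternative hypothesis for the interaction-enrichment test:
#' two disjoint gene sets A (ABA-dependent-like) and B (ABA-independent-like)
#' whose cross-set edge probability is `enrichment_factor` times the
#' background density, plus `n_core_A`/`n_core_B` "core" genes that receive an
#' extra excess of cross edges (`core_multiplier` times the expected
#' background cross-degree).
#'
#' @param size_A,size_B Sizes of the two planted sets.
#' @param enrichment_factor Multiplier (>= 1) on the cross-set edge
#'   probability relative to background density; 1 plants nothing (exact null).
#' @param n_core_A,n_core_B Number of core genes per set.
#' @param core_multiplier Core excess: each core gene receives extra cross
#'   edges totalling `core_multiplier` times its expected background
#'   cross-degree. Default 10.
#' @param seed Integer seed.
#' @return An object of class `crosstalk_spec`.
#' @export
crosstalk_spec <- function(size_A, size_B, enrichment_factor = 1,
                           n_core_A = 0, n_core_B = 0, core_multiplier = 10,
                           seed = 1L) {
  stopifnot(size_A >= 1, size_B >= 1, enrichment_factor >= 1,
            n_core_A >= 0, n_core_B >= 0, core_multiplier >= 1)
  if (n_core_A > size_A) stop("n_core_A > size_A")
  if (n_core_B > size_B) stop("n_core_B > size_B")
  structure(list(size_A = as.integer(size_A), size_B = as.integer(size_B),
                 enrichment_factor = enrichment_factor,
                 n_core_A = as.integer(n_core_A), n_core_B = as.integer(n_core_B),
                 core_multiplier = core_multiplier, seed = as.integer(seed)),
            class = "crosstalk_spec")
}

#' Plant cross-set edge enrichment in a network
#'
#' Selects disjoint sets A and B, then adds edges between them so the
#' realized cross-set edge probability is `enrichment_factor` times the
#' background density (existing background cross edges are left in place and
#' `(enrichment_factor - 1) * |A| * |B| * density` new ones are added). Core
#' genes additionally receive extra cross edges up to `core_multiplier` times
#' the expected background cross-degree. With `enrichment_factor = 1` and no
#' cores the input graph is returned unchanged, so the null fixture carries
#' no planted signal.
#'
#' @param net An `igraph` network.
#' @param spec A [crosstalk_spec()].
#' @return A list with elements `network` (the augmented graph) and
#'   `manifest` (ground truth: sets, core flags, realized per-gene and global
#'   cross-edge counts, expected background count, seeds).
#' @export
plant_crosstalk <- function(net, spec) {
  stopifnot(inherits(spec, "crosstalk_spec"))
  n <- igraph::vcount(net)
  if (spec$size_A + spec$size_B > n)
    stop("size_A + size_B exceeds number of nodes")
  set.seed(spec$seed)
  nodes <- igraph::V(net)$name
  picked <- sample(nodes, spec$size_A + spec$size_B)
  set_A <- sort(picked[seq_len(spec$size_A)])
  set_B <- sort(picked[spec$size_A + seq_len(spec$size_B)])
  core_A <- sort(sample(set_A, spec$n_core_A))
  core_B <- sort(sample(set_B, spec$n_core_B))
  p_bg <- igraph::edge_density(net)
  expected_bg <- spec$size_A * spec$size_B * p_bg

  g <- net
  add_cross_edges <- function(g, n_add, from_pool, to_pool) {
    if (n_add <= 0) return(g)
    el <- igraph::as_edgelist(g, names = TRUE)
    existing <- c(paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
    cand <- expand.grid(a = from_pool, b = to_pool,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    cand <- cand[cand$a != cand$b & !(paste(cand$a, cand$b) %in% existing), ,
                 drop = FALSE]
    if (nrow(cand) < n_add)
      stop("requested enrichment unreachable: need ", n_add,
           " new cross edges but only ", nrow(cand), " non-adjacent pairs remain")
    pick <- cand[sample(nrow(cand), n_add), , drop = FALSE]
    igraph::add_edges(g, as.vector(rbind(pick$a, pick$b)),
                      weight = runif(n_add, 0.5, 1))
  }

  n_extra <- round((spec$enrichment_factor - 1) * expected_bg)
  g <- add_cross_edges(g, n_extra, set_A, set_B)

  core_excess_A <- round(spec$core_multiplier * spec$size_B * p_bg)
  for (gene in core_A) g <- add_cross_edges(g, core_excess_A, gene, set_B)
  core_excess_B <- round(spec$core_multiplier * spec$size_A * p_bg)
  for (gene in core_B) g <- add_cross_edges(g, core_excess_B, gene, set_A)

  inA <- nodes %in% set_A
  inB <- nodes %in% set_B
  el <- igraph::as_edgelist(g, names = TRUE)
  cross <- (el[, 1] %in% set_A & el[, 2] %in% set_B) |
           (el[, 1] %in% set_B & el[, 2] %in% set_A)
  cross_genes <- c(el[cross, 1], el[cross, 2])
  per_gene <- table(factor(cross_genes[cross_genes %in% c(set_A, set_B)],
                           levels = c(set_A, set_B)))
  manifest <- list(
    set_A = set_A, set_B = set_B, core_A = core_A, core_B = core_B,
    enrichment_factor = spec$enrichment_factor,
    core_multiplier = spec$core_multiplier,
    p_background = p_bg,
    expected_background_cross = expected_bg,
    n_cross_added = n_extra,
    core_excess_per_gene = c(A = core_excess_A, B = core_excess_B),
    realized_cross_total = sum(cross),
    realized_cross_per_gene = setNames(as.integer(per_gene), names(per_gene)),
    seed = spec$seed)
  list(network = g, manifest = manifest)
}

#' Specification of a synthetic contrast table
#'
#' Defines per-gene ground-truth DEG classes and the noise model used to fill
#' in log2 fold changes and p-values for the four contrasts (drought day 10,
#' drought day 12, rewatered day 2, ABA 4 h — each versus its control).
#' Responsive contrasts draw |log2FC| as `1 + Exp(mean = effect_log2fc - 1)`
#' (so two-fold is the guaranteed floor) and p-values from a Beta(0.5, 20)
#' truncated below the calling threshold; non-responsive contrasts draw
#' |log2FC| uniformly below 1 and p uniform on (0, 1), so with
#' `label_noise = 0` every gene passes exactly the contrasts its class
#' implies.
#'
#' @param class_counts Named integer vector over
#'   `ABA_DEPENDENT`, `ABA_INDEPENDENT`, `NOT_RECOVERED`, `NON_DEG` (missing
#'   names count 0).
#' @param effect_log2fc Mean planted |log2FC| for responsive contrasts
#'   (> 1; default 3).
#' @param de_p_shape Two Beta shape parameters for significant p-values
#'   (default `c(0.5, 20)`).
#' @param max_p Calling threshold the planted p-values must beat (default 0.05).
#' @param label_noise Per-gene probability of corrupting one defining
#'   contrast (default 0).
#' @param seed Integer seed.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(class_counts, effect_log2fc = 3,
                                de_p_shape = c(0.5, 20), max_p = 0.05,
                                label_noise = 0, seed = 1L) {
  counts <- setNames(integer(length(.deg_classes)), .deg_classes)
  stopifnot(all(names(class_counts) %in% .deg_classes))
  counts[names(class_counts)] <- as.integer(class_counts)
  stopifnot(all(counts >= 0), sum(counts) >= 1, effect_log2fc > 1,
            length(de_p_shape) == 2, all(de_p_shape > 0),
            max_p > 0, max_p < 1, label_noise >= 0, label_noise <= 1)
  structure(list(class_counts = counts, n_genes = sum(counts),
                 effect_log2fc = effect_log2fc, de_p_shape = de_p_shape,
                 max_p = max_p, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

# draw p-values from Beta(shape) truncated to [0, max_p)
.rtrunc_beta <- function(n, shape, max_p) {
  qbeta(runif(n) * pbeta(max_p, shape[1], shape[2]), shape[1], shape[2])
}

# fill one gene-block of responsive/non-responsive contrast values
.sim_contrast_block <- function(n, responsive, spec) {
  if (responsive) {
    fc <- sample(c(-1, 1), n, replace = TRUE) *
      (1 + rexp(n, rate = 1 / (spec$effect_log2fc - 1)))
    p <- .rtrunc_beta(n, spec$de_p_shape, spec$max_p)
  } else {
    fc <- runif(n, -0.95, 0.95)
    p <- runif(n)
  }
  list(fc = fc, p = p)
}

#' Generate a synthetic contrast table with known classes
#'
#' @param spec An [expression_sim_spec()].
#' @param gene_ids Optional gene identifiers (default synthetic ids); length
#'   must equal the spec's total gene count.
#' @param classes Optional character vector of per-gene classes aligned with
#'   `gene_ids`, overriding the spec's count-based layout (used to tie the
#'   table to network-planted sets). Class totals must match the spec.
#' @return A list with `table` (data.frame: `gene_id`, then
#'   `log2fc_<contrast>`, `p_<contrast>` for the four contrasts) and
#'   `manifest` (true class per gene, noise-corrupted genes, seed).
#' @export
generate_contrast_table <- function(spec, gene_ids = NULL, classes = NULL) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  n <- spec$n_genes
  if (is.null(gene_ids)) gene_ids <- syn_gene_ids(n)
  stopifnot(length(gene_ids) == n, !anyDuplicated(gene_ids))
  if (is.null(classes)) {
    classes <- rep(.deg_classes, spec$class_counts[.deg_classes])
  } else {
    stopifnot(length(classes) == n, all(classes %in% .deg_classes))
    tab <- table(factor(classes, levels = .deg_classes))
    if (!all(tab == spec$class_counts[.deg_classes]))
      stop("class totals of `classes` disagree with spec$class_counts")
  }
  set.seed(spec$seed)

  # which contrasts each class responds in
  responds <- list(
    ABA_DEPENDENT   = c(drought10 = TRUE,  drought12 = TRUE,  rewater2 = FALSE, aba4 = TRUE),
    ABA_INDEPENDENT = c(drought10 = TRUE,  drought12 = TRUE,  rewater2 = FALSE, aba4 = FALSE),
    NOT_RECOVERED   = c(drought10 = TRUE,  drought12 = TRUE,  rewater2 = TRUE,  aba4 = FALSE),
    NON_DEG         = c(drought10 = FALSE, drought12 = FALSE, rewater2 = FALSE, aba4 = FALSE))

  tbl <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (ct in .contrasts) {
    fc <- numeric(n); p <- numeric(n)
    for (cl in .deg_classes) {
      idx <- which(classes == cl)
      if (!length(idx)) next
      blk <- .sim_contrast_block(length(idx), responds[[cl]][[ct]], spec)
      fc[idx] <- blk$fc; p[idx] <- blk$p
    }
    tbl[[paste0("log2fc_", ct)]] <- fc
    tbl[[paste0("p_", ct)]] <- p
  }

  noisy <- logical(n)
  if (spec$label_noise > 0) {
    noisy <- runif(n) < spec$label_noise
    for (i in which(noisy)) {
      ct <- sample(.contrasts, 1)
      was <- responds[[classes[i]]][[ct]]
      blk <- .sim_contrast_block(1, !was, spec)
      tbl[i, paste0("log2fc_", ct)] <- blk$fc
      tbl[i, paste0("p_", ct)] <- blk$p
    }
  }
  manifest <- list(classes = setNames(classes, gene_ids),
                   class_counts = spec$class_counts,
                   noisy_genes = gene_ids[noisy], seed = spec$seed)
  list(table = tbl, manifest = manifest)
}

#' Generate a log-normal expression matrix with planted class correlation
#'
#' Genes of the same DEG class share a latent class factor; the three
#' drought-responsive classes additionally share a common "drought" factor,
#' so within-class correlation is `within_class_cor`, correlation between
#' genes of different responsive classes is `between_deg_cor`, and
#' correlation involving `NON_DEG` genes is 0. Values are
#' `exp(mu_g + signal)`, an FPKM-like positive abundance scale.
#'
#' @param spec An [expression_sim_spec()].
#' @param n_samples Number of samples (>= 3).
#' @param within_class_cor Within-class correlation on the log scale,
#'   in \[0, 1) (default 0.6).
#' @param between_deg_cor Correlation between genes of different responsive
#'   classes (default 0.3; must be <= `within_class_cor`).
#' @param gene_ids,classes As in [generate_contrast_table()].
#' @return A numeric matrix (genes x samples) with gene ids as rownames.
#' @export
generate_expression_matrix <- function(spec, n_samples,
                                       within_class_cor = 0.6,
                                       between_deg_cor = 0.3,
                                       gene_ids = NULL, classes = NULL) {
  stopifnot(inherits(spec, "expression_sim_spec"), n_samples >= 3,
            within_class_cor >= 0, within_class_cor < 1,
            between_deg_cor >= 0, between_deg_cor <= within_class_cor)
  n <- spec$n_genes
  if (is.null(gene_ids)) gene_ids <- syn_gene_ids(n)
  if (is.null(classes)) classes <- rep(.deg_classes, spec$class_counts[.deg_classes])
  set.seed(spec$seed + 1L)  # decoupled from the contrast-table stream

  shared <- rnorm(n_samples)                      # common drought factor
  class_fac <- sapply(.deg_classes, function(cl) rnorm(n_samples))
  responsive <- classes %in% c("ABA_DEPENDENT", "ABA_INDEPENDENT", "NOT_RECOVERED")
  # NON_DEG genes are an uncorrelated background pool; responsive classes mix
  # a shared drought factor with a class-specific factor
  w_shared <- ifelse(responsive, sqrt(between_deg_cor), 0)
  w_class <- ifelse(responsive, sqrt(within_class_cor - w_shared^2), 0)
  w_noise <- sqrt(1 - w_shared^2 - w_class^2)

  mu <- rnorm(n, mean = log(100), sd = 1)
  x <- matrix(rnorm(n * n_samples), n, n_samples)
  for (i in seq_len(n)) {
    x[i, ] <- mu[i] + w_shared[i] * shared +
      w_class[i] * class_fac[, classes[i]] + w_noise[i] * x[i, ]
  }
  m <- exp(x)
  rownames(m) <- gene_ids
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  m
}

#' Simulate a complete crosstalk study with ground truth
#'
#' Convenience wrapper wiring the generators together the way the analysis
#' consumes them: a configuration-model PPI network with planted A-B
#' enrichment, a contrast table whose ABA-dependent genes are exactly set A
#' and ABA-independent genes exactly set B, and (optionally) an expression
#' matrix sharing the planted class structure.
#'
#' @param n_nodes,mean_degree,model,seed Network parameters
#'   (see [network_spec()]). The default mean degree 50 matches the
#'   connectivity of a genome-scale predicted interactome.
#' @param size_A,size_B,enrichment_factor,n_core_A,n_core_B,core_multiplier
#'   Planting parameters (see [crosstalk_spec()]).
#' @param n_not_recovered Genes planted as drought-responsive but not
#'   recovered by rewatering (default 40).
#' @param effect_log2fc,label_noise Contrast-table noise model
#'   (see [expression_sim_spec()]).
#' @param n_samples Samples for the expression matrix; `0` skips it.
#' @param within_class_cor,between_deg_cor Planted co-expression structure
#'   (see [generate_expression_matrix()]).
#' @return A list: `network`, `contrast_table`, `expression` (or `NULL`),
#'   `sets` (A, B, not_recovered, pool), and `manifest` combining the network
#'   and table ground truth.
#' @export
simulate_study <- function(n_nodes = 2000, mean_degree = 50,
                           model = "configuration_poisson",
                           size_A = 50, size_B = 200,
                           enrichment_factor = 1, n_core_A = 0, n_core_B = 0,
                           core_multiplier = 10, n_not_recovered = 40,
                           effect_log2fc = 3, label_noise = 0,
                           n_samples = 50, within_class_cor = 0.6,
                           between_deg_cor = 0.3, seed = 1L) {
  seed <- as.integer(seed)
  net <- generate_network(network_spec(n_nodes, mean_degree, model, seed = seed))
  planted <- plant_crosstalk(net, crosstalk_spec(
    size_A, size_B, enrichment_factor, n_core_A, n_core_B, core_multiplier,
    seed = seed + 1L))
  nodes <- igraph::V(planted$network)$name
  rest <- setdiff(nodes, c(planted$manifest$set_A, planted$manifest$set_B))
  set.seed(seed + 2L)
  nr <- sort(sample(rest, n_not_recovered))
  classes <- setNames(rep("NON_DEG", length(nodes)), nodes)
  classes[planted$manifest$set_A] <- "ABA_DEPENDENT"
  classes[planted$manifest$set_B] <- "ABA_INDEPENDENT"
  classes[nr] <- "NOT_RECOVERED"
  counts <- table(factor(classes, levels = .deg_classes))
  espec <- expression_sim_spec(setNames(as.integer(counts), names(counts)),
                               effect_log2fc = effect_log2fc,
                               label_noise = label_noise, seed = seed + 3L)
  ct <- generate_contrast_table(espec, gene_ids = nodes, classes = unname(classes))
  expr <- if (n_samples >= 3)
    generate_expression_matrix(espec, n_samples,
                               within_class_cor = within_class_cor,
                               between_deg_cor = between_deg_cor,
                               gene_ids = nodes,
                               classes = unname(classes)) else NULL
  manifest <- c(planted$manifest, ct$manifest["noisy_genes"],
                list(classes = ct$manifest$classes,
                     not_recovered = nr, master_seed = seed))
  list(network = planted$network, contrast_table = ct$table, expression = expr,
       sets = list(A = planted$manifest$set_A, B = planted$manifest$set_B,
                   not_recovered = nr,
                   pool = sort(setdiff(rest, nr))),
       manifest = manifest)
}
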