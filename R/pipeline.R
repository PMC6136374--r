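#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. When `contrast_table`
#' or `edge_list` paths are `NULL`, inputs are simulated from the synthetic
#' module with the simulation parameters below, which makes the packaged demo
#' self-contained.
#'
#' @param out_dir Output directory (created if needed).
#' @param contrast_table,edge_list,expression Optional input file paths
#'   (TSV). `NULL` means simulate.
#' @param min_fold_change,max_p DEG thresholds (see [deg_thresholds()]).
#' @param require_concordant_sign See [classify_degs()].
#' @param R Randomized networks in the null ensemble (default 1000).
#' @param swap_multiplier Swap attempts per edge (default 10).
#' @param alpha Core-gene empirical-p threshold (default 0.05).
#' @param top_fraction Co-expression link quantile (default 0.01).
#' @param n_resamples Resampled set pairs for the Z-score comparison and the
#'   co-expression baseline (default 100).
#' @param subsample_fraction DEG-side subsample fraction (default 0.8).
#' @param min_edge_weight Discard network edges below this confidence.
#' @param pseudocount_p Use the `(r+1)/(R+1)` empirical-p estimator.
#' @param sim Named list of [simulate_study()] arguments used when inputs
#'   are simulated.
#' @param seed Master seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            contrast_table = NULL, edge_list = NULL,
                            expression = NULL,
                            min_fold_change = 2, max_p = 0.05,
                            require_concordant_sign = FALSE,
                            R = 1000, swap_multiplier = 10, alpha = 0.05,
                            top_fraction = 0.01, n_resamples = 100,
                            subsample_fraction = 0.8, min_edge_weight = 0,
                            pseudocount_p = FALSE, sim = list(), seed = 1L) {
  stopifnot(R >= 1, swap_multiplier >= 1, alpha > 0, alpha <= 1,
            top_fraction > 0, top_fraction <= 1, n_resamples >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            min_edge_weight >= 0)
  deg_thresholds(min_fold_change, max_p)  # range validation
  structure(list(out_dir = out_dir, contrast_table = contrast_table,
                 edge_list = edge_list, expression = expression,
                 min_fold_change = min_fold_change, max_p = max_p,
                 require_concordant_sign = require_concordant_sign,
                 R = as.integer(R), swap_multiplier = swap_multiplier,
                 alpha = alpha, top_fraction = top_fraction,
                 n_resamples = as.integer(n_resamples),
                 subsample_fraction = subsample_fraction,
                 min_edge_weight = min_edge_weight,
                 pseudocount_p = pseudocount_p, sim = sim,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Packaged demo configuration
#'
#' Simulated inputs (2000-gene network with planted five-fold cross-set
#' enrichment and planted cores) at a reduced ensemble size, for smoke tests
#' and examples.
#'
#' @inheritParams pipeline_config
#' @export
demo_config <- function(out_dir, seed = 1L, R = 200) {
  pipeline_config(out_dir, R = R, n_resamples = 50, seed = seed,
                  sim = list(n_nodes = 2000, mean_degree = 50,
                             size_A = 50, size_B = 200,
                             enrichment_factor = 5, n_core_A = 10,
                             n_core_B = 20, n_samples = 50))
}

.flat_config <- function(config) {
  flat <- config[setdiff(names(config), "sim")]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  sim <- config$sim
  if (length(sim)) names(sim) <- paste0("sim.", names(sim))
  c(lapply(flat, as.character), lapply(sim, as.character))
}

#' Run the full crosstalk analysis pipeline
#'
#' Executes classify -> randomize -> enrich -> report on the configured
#' inputs (or on simulated inputs with ground truth), writing every artifact
#' to `config$out_dir`: class assignments, per-gene enrichment, global
#' Z-score summary, Z-score comparison, optional co-expression enrichment,
#' the core subnetwork as SIF and GraphML, the echoed configuration, a run
#' log, and a JSON manifest with MD5 checksums of every written file. Reruns
#' with the same config and inputs are byte-identical for all TSV/SIF
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (file -> checksum), and `results` (the in-memory objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir) || file.access(config$out_dir, 2) != 0)
    stop("output directory not writable: ", config$out_dir)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("abacross ", as.character(utils::packageVersion("abacross")),
      " pipeline run, master seed ", config$seed)

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  if (is.null(config$contrast_table) || is.null(config$edge_list)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    study <- do.call(simulate_study, sim_args)
    net <- study$network
    tbl <- study$contrast_table
    expr <- study$expression
    truth <- study$manifest
    say("stage simulate: ", igraph::vcount(net), " nodes, ",
        igraph::ecount(net), " edges, ", nrow(tbl), " genes")
  } else {
    net <- read_edge_list(config$edge_list, min_weight = config$min_edge_weight)
    tbl <- read_contrast_table(config$contrast_table)
    expr <- if (!is.null(config$expression))
      read_expression_matrix(config$expression) else NULL
    say("stage load: ", igraph::vcount(net), " nodes, ",
        igraph::ecount(net), " edges, ", nrow(tbl), " genes")
  }

  # --- classify -------------------------------------------------------
  thr <- deg_thresholds(config$min_fold_change, config$max_p)
  classes <- classify_degs(tbl, thr, config$require_concordant_sign)
  counts <- table(classes$class)
  say("stage classify: ", paste(names(counts), as.integer(counts),
                                sep = "=", collapse = ", "))
  set_A <- classes$gene_id[classes$class == "ABA_DEPENDENT"]
  set_B <- classes$gene_id[classes$class == "ABA_INDEPENDENT"]
  pool <- classes$gene_id[classes$class == "NON_DEG"]
  if (!length(set_A) || !length(set_B))
    stop("stage classify: one of the DEG classes is empty; cannot test crosstalk")

  # --- randomize ------------------------------------------------------
  ensemble <- build_ensemble(net, R = config$R,
                             swap_multiplier = config$swap_multiplier,
                             seed = config$seed + 10L)
  say("stage randomize: R=", ensemble$R, ", swap acceptance ",
      signif(ensemble$acceptance_rate, 3))

  # --- enrich ---------------------------------------------------------
  records <- per_gene_enrichment(net, ensemble, set_A, set_B,
                                 pseudocount = config$pseudocount_p)
  cores <- select_core_components(records, alpha = config$alpha)
  glob <- global_enrichment(net, ensemble, set_A, set_B)
  zcmp <- compare_zscores(net, ensemble, set_A, set_B, pool,
                          n_resamples = config$n_resamples,
                          subsample_fraction = config$subsample_fraction,
                          seed = config$seed + 20L)
  coex <- NULL
  if (!is.null(expr)) {
    coex <- coexpression_enrichment(expr, intersect(set_A, rownames(expr)),
                                    intersect(set_B, rownames(expr)),
                                    intersect(pool, rownames(expr)),
                                    top_fraction = config$top_fraction,
                                    n_resamples = config$n_resamples,
                                    seed = config$seed + 30L)
  }
  subnet <- extract_core_subnetwork(net, cores$core_A, cores$core_B, records)
  say("stage enrich: global Z=", signif(glob$z_score, 5),
      " (observed ", glob$n_observed, ", null ", signif(glob$mu_null, 5),
      " +/- ", signif(glob$sd_null, 5), "); cores A=",
      length(cores$core_A), " B=", length(cores$core_B),
      "; core subnetwork edges cross=", subnet$n_cross_edges,
      " within=", subnet$n_within_edges)
  if (!is.null(coex))
    say("stage enrich: coexpression links=", coex$n_links_observed,
        ", fold=", signif(coex$fold_enrichment, 4))

  # --- report ---------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  write.table(classes, out("classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rec_out <- records
  rec_out[c("null_mean", "null_sd", "empirical_p", "bh_q")] <-
    lapply(rec_out[c("null_mean", "null_sd", "empirical_p", "bh_q")],
           function(x) sprintf("%.10g", x))
  write.table(rec_out, out("per_gene_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gsum <- data.frame(n_observed = glob$n_observed,
                     mu_null = sprintf("%.10g", glob$mu_null),
                     sd_null = sprintf("%.10g", glob$sd_null),
                     z_score = sprintf("%.10g", glob$z_score),
                     R = ensemble$R,
                     t_statistic = sprintf("%.10g", zcmp$t_statistic),
                     t_p_value = sprintf("%.10g", zcmp$p_value),
                     n_core_A = length(cores$core_A),
                     n_core_B = length(cores$core_B))
  if (!is.null(coex)) {
    gsum$coexpression_links <- coex$n_links_observed
    gsum$coexpression_fold <- sprintf("%.10g", coex$fold_enrichment)
  }
  write.table(gsum, out("global_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(z_deg = sprintf("%.10g", zcmp$z_deg),
                         z_nondeg = sprintf("%.10g", zcmp$z_nondeg)),
              out("zscore_comparison.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (set in c("ABA_DEPENDENT", "ABA_INDEPENDENT", "NOT_RECOVERED")) {
    writeLines(sort(classes$gene_id[classes$class == set]),
               out(paste0(tolower(set), "_genes.txt")))
  }
  write_sif(subnet, out("core_subnetwork.sif"))
  write_graphml(subnet, out("core_subnetwork.graphml"))
  writeLines(paste0(names(.flat_config(config)), ": ",
                    unlist(.flat_config(config))), out("config_echo.txt"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(classes = as.list(truth$classes),
           core_A = truth$core_A, core_B = truth$core_B,
           realized_cross_total = truth$realized_cross_total,
           master_seed = truth$master_seed),
      out("ground_truth_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  writeLines(log, out("run_log.txt"))

  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(checksums) <- files
  jsonlite::write_json(checksums, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(status = 0L, manifest = checksums,
                 results = list(classes = classes, records = records,
                                cores = cores, global = glob, zcomp = zcmp,
                                coexpression = coex, subnetwork = subnet,
                                ensemble_acceptance = ensemble$acceptance_rate,
                                truth = truth)))
}
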