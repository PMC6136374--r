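#' DEG calling thresholds
#'
#' The study-standard rule: at least `min_fold_change`-fold change
#' (inclusive, i.e. |log2FC| >= log2(min_fold_change)) and p strictly below
#' `max_p`.
#'
#' @param min_fold_change Minimum fold change (> 1), default 2.
#' @param max_p Maximum p-value (strict), default 0.05.
#' @return An object of class `deg_thresholds`.
#' @export
deg_thresholds <- function(min_fold_change = 2, max_p = 0.05) {
  stopifnot(min_fold_change > 1, max_p > 0, max_p < 1)
  structure(list(min_fold_change = min_fold_change, max_p = max_p),
            class = "deg_thresholds")
}

.check_contrast_table <- function(table, contrasts = .contrasts) {
  stopifnot(is.data.frame(table), "gene_id" %in% names(table))
  if (anyDuplicated(table$gene_id)) stop("duplicate gene_ids in contrast table")
  for (ct in contrasts) {
    fc <- paste0("log2fc_", ct); p <- paste0("p_", ct)
    if (!fc %in% names(table) || !p %in% names(table))
      stop("contrast '", ct, "' missing from table (need columns ", fc, ", ", p, ")")
    pv <- table[[p]]
    if (any(pv < 0 | pv > 1, na.rm = TRUE))
      stop("p-values for contrast '", ct, "' outside [0, 1]")
  }
  invisible(TRUE)
}

# per-gene logical DEG call for one contrast; NA values give FALSE and are
# tallied in the "n_missing" attribute
.deg_call <- function(table, contrast, thresholds) {
  fc <- table[[paste0("log2fc_", contrast)]]
  p <- table[[paste0("p_", contrast)]]
  miss <- is.na(fc) | is.na(p)
  call <- !miss & abs(fc) >= log2(thresholds$min_fold_change) & p < thresholds$max_p
  attr(call, "n_missing") <- sum(miss)
  call
}

#' Call differentially expressed genes in one contrast
#'
#' A gene is a DEG when |log2FC| >= log2(min_fold_change) (fold change "at
#' least" the threshold, so exactly two-fold qualifies) and p < max_p
#' (strict). Genes with a missing fold change or p-value in the contrast are
#' excluded and counted in a warning.
#'
#' @param table Contrast table (data.frame with `gene_id` and
#'   `log2fc_<contrast>`, `p_<contrast>` columns).
#' @param contrast One of `"drought10"`, `"drought12"`, `"rewater2"`, `"aba4"`.
#' @param thresholds A [deg_thresholds()].
#' @return Character vector of DEG gene ids.
#' @examples
#' tbl <- data.frame(gene_id = c("g1", "g2"),
#'                   log2fc_drought10 = c(1.0, 3.0),
#'                   p_drought10 = c(0.049, 0.06))
#' call_contrast_degs(tbl, "drought10")   # g1 only
#' @export
call_contrast_degs <- function(table, contrast, thresholds = deg_thresholds()) {
  if (!contrast %in% .contrasts &&
      !all(paste0(c("log2fc_", "p_"), contrast) %in% names(table)))
    stop("unknown contrast: ", contrast)
  .check_contrast_table(table, contrast)
  call <- .deg_call(table, contrast, thresholds)
  if (attr(call, "n_missing") > 0)
    warning(attr(call, "n_missing"), " gene(s) with missing values excluded from contrast ",
            contrast)
  table$gene_id[call]
}

#' Classify drought-responsive genes into ABA-pathway classes
#'
#' Drought-responsive genes are DEGs after 10 or 12 days of drought. Among
#' them, genes still differentially expressed 2 days after rewatering are
#' `NOT_RECOVERED` and set aside; the recovered remainder is split by the
#' ABA-treatment contrast into `ABA_DEPENDENT` (also an ABA DEG) and
#' `ABA_INDEPENDENT` (not an ABA DEG). Everything else is `NON_DEG`. The four
#' classes partition the input gene universe.
#'
#' @inheritParams call_contrast_degs
#' @param require_concordant_sign If `TRUE`, `ABA_DEPENDENT` additionally
#'   requires the ABA log2FC to agree in sign with a passing drought log2FC;
#'   sign-discordant genes fall to `ABA_INDEPENDENT`. Default `FALSE` (sets
#'   are intersected without sign constraints).
#' @return A data.frame with columns `gene_id` and `class` (factor with
#'   levels `ABA_DEPENDENT`, `ABA_INDEPENDENT`, `NOT_RECOVERED`, `NON_DEG`).
#' @export
classify_degs <- function(table, thresholds = deg_thresholds(),
                          require_concordant_sign = FALSE) {
  .check_contrast_table(table)
  d10 <- .deg_call(table, "drought10", thresholds)
  d12 <- .deg_call(table, "drought12", thresholds)
  rw <- .deg_call(table, "rewater2", thresholds)
  aba <- .deg_call(table, "aba4", thresholds)

  drought <- d10 | d12
  recovered <- !rw
  aba_dep <- drought & recovered & aba
  if (require_concordant_sign) {
    s_aba <- sign(table$log2fc_aba4)
    concord <- (d10 & sign(table$log2fc_drought10) == s_aba) |
               (d12 & sign(table$log2fc_drought12) == s_aba)
    concord[is.na(concord)] <- FALSE
    aba_dep <- aba_dep & concord
  }
  cls <- rep("NON_DEG", nrow(table))
  cls[drought & !recovered] <- "NOT_RECOVERED"
  cls[aba_dep] <- "ABA_DEPENDENT"
  cls[drought & recovered & !aba_dep] <- "ABA_INDEPENDENT"
  data.frame(gene_id = table$gene_id,
             class = factor(cls, levels = .deg_classes),
             stringsAsFactors = FALSE)
}

#' Gene-detection saturation curve by read subsampling
#'
#' Subsamples reads without replacement from a per-gene read-count vector
#' (multivariate hypergeometric) and counts genes detected with at least
#' `min_reads` reads at each depth, averaged over `n_reps` replicates. Used
#' to check that sequencing depth approached saturation.
#'
#' @param read_counts Non-negative integer vector of per-gene read counts for
#'   one library.
#' @param depths Integer vector of subsample sizes, each <= total reads.
#' @param min_reads Detection threshold (default 5 reads).
#' @param n_reps Replicates per depth (default 10).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `depth` and `mean_detected`.
#' @export
saturation_curve <- function(read_counts, depths, min_reads = 5, n_reps = 10,
                             seed = NULL) {
  stopifnot(all(read_counts >= 0), all(read_counts == round(read_counts)),
            n_reps >= 1, min_reads >= 1)
  total <- sum(read_counts)
  if (any(depths > total))
    stop("depth ", max(depths), " exceeds library size ", total)
  if (!is.null(seed)) set.seed(seed)
  detected <- sapply(depths, function(k) {
    mean(vapply(seq_len(n_reps), function(r) {
      sub <- .rmvhyper(read_counts, k)
      sum(sub >= min_reads)
    }, numeric(1)))
  })
  data.frame(depth = depths, mean_detected = detected)
}

# one multivariate hypergeometric draw: k items without replacement from urns
# sized `counts` (sequential conditional rhyper)
.rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  for (i in seq_len(n)) {
    if (k <= 0) break
    if (remaining == counts[i]) { out[i] <- k; k <- 0; break }
    out[i] <- rhyper(1, counts[i], remaining - counts[i], k)
    k <- k - out[i]
    remaining <- remaining - counts[i]
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-ddCt` with
#' `ddCt = (ct_target_treated - ct_ref_treated) - (ct_target_control - ct_ref_control)`,
#' the standard qPCR relative-quantification formula (target normalized to a
#' reference gene, treated relative to control).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (vectorized, finite).
#' @return Relative expression level(s).
#' @examples
#' ddct_relative_expression(20, 18, 24, 18)  # ddCt = -4 -> 16
#' @export
ddct_relative_expression <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
          (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Concordance between two fold-change measurement methods
#'
#' Pearson product-moment correlation with a two-sided t-distributed p-value,
#' e.g. to assess agreement between RT-qPCR and RNA-seq log2 fold changes.
#'
#' @param x,y Paired numeric vectors (equal length >= 3, no missing values).
#' @return A list with `r`, `p_value` and `n`.
#' @export
method_concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
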