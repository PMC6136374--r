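#' Read an interaction network from an edge-list TSV
#'
#' Expects at least two tab-separated columns (`gene_a`, `gene_b`), an
#' optional numeric weight column and an optional 0/1 experimental
#' verification flag. A header row is detected when the weight field of the
#' first row is non-numeric. Gene ids are uppercased for matching. Self-loops
#' are dropped and duplicate rows (including reversed duplicates) collapsed
#' keeping the maximum weight; both counts are reported in a message and as
#' graph attributes `n_selfloops_dropped` / `n_duplicates_collapsed`.
#'
#' @param path Path to the TSV file.
#' @param min_weight Drop edges with weight below this value (default 0,
#'   keep all).
#' @return A simple undirected `igraph` with `weight` (and `verified`, if
#'   present) edge attributes.
#' @export
read_edge_list <- function(path, min_weight = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge-list file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", path,
         " (need at least 2 tab-separated fields)")
  start <- 1L
  if (nf[1] >= 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3]))))
    start <- 2L
  if (start > length(lines)) stop("edge-list file has a header but no data: ", path)
  rows <- fields[start:length(fields)]
  a <- toupper(vapply(rows, `[[`, "", 1))
  b <- toupper(vapply(rows, `[[`, "", 2))
  w <- vapply(rows, function(r) {
    if (length(r) >= 3) suppressWarnings(as.numeric(r[3])) else 1
  }, numeric(1))
  if (anyNA(w)) {
    line <- which(is.na(w))[1] + start - 1L
    stop("malformed row at line ", line, " of ", path, " (non-numeric weight)")
  }
  v <- vapply(rows, function(r) {
    if (length(r) >= 4) suppressWarnings(as.integer(r[4])) else NA_integer_
  }, integer(1))

  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; w <- w[!self]; v <- v[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  n_dup <- sum(duplicated(key))
  ord <- order(key, -w)
  keep <- !duplicated(key[ord])
  d <- data.frame(from = lo[ord][keep], to = hi[ord][keep],
                  weight = w[ord][keep], stringsAsFactors = FALSE)
  vv <- v[ord][keep]
  if (!all(is.na(vv))) d$verified <- ifelse(is.na(vv), 0L, vv)
  if (min_weight > 0) d <- d[d$weight >= min_weight, , drop = FALSE]
  if (!nrow(d)) stop("no edges left after filtering: ", path)
  if (n_self || n_dup)
    message("read_edge_list: dropped ", n_self, " self-loop(s), collapsed ",
            n_dup, " duplicate row(s)")
  g <- igraph::graph_from_data_frame(d, directed = FALSE)
  g$n_selfloops_dropped <- n_self
  g$n_duplicates_collapsed <- n_dup
  g
}

#' Write a network as an edge-list TSV
#'
#' Canonical deterministic form: lexicographically ordered endpoint pairs,
#' sorted rows, header `gene_a  gene_b  weight`.
#'
#' @param net An `igraph` with named vertices.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  d <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                  gene_b = pmax(el[, 1], el[, 2]),
                  weight = sprintf("%.6g", w), stringsAsFactors = FALSE)
  v <- igraph::E(net)$verified
  if (!is.null(v)) d$verified <- v
  d <- d[order(d$gene_a, d$gene_b), , drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in SIF format
#'
#' Simple interaction format for Cytoscape, one `geneA pp geneB` line per
#' edge, deterministically ordered. An empty network yields a valid empty
#' file.
#'
#' @inheritParams write_edge_list
#' @export
write_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b)
    writeLines(paste(a[ord], "pp", b[ord], sep = "\t"), path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' Write / read a network in GraphML format
#'
#' Thin wrappers over [igraph::write_graph()] / [igraph::read_graph()] so
#' annotated subnetworks round-trip with their node and edge attributes for
#' Cytoscape.
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read / write a contrast table TSV
#'
#' Tab-delimited with a header: `gene_id`, then `log2fc_<contrast>` and
#' `p_<contrast>` for contrasts `drought10`, `drought12`, `rewater2`, `aba4`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_contrast_table <- function(path) {
  tbl <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  .check_contrast_table(tbl)
  tbl$gene_id <- toupper(tbl$gene_id)
  tbl
}

#' @rdname read_contrast_table
#' @param table Contrast table data.frame.
#' @export
write_contrast_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(x) sprintf("%.10g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV (genes x samples)
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_expression_matrix
#' @param expr Numeric matrix, genes x samples.
#' @export
write_expression_matrix <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr),
                  apply(expr, 2, function(x) sprintf("%.10g", x)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
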