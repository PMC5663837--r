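# circRNA expression quantities (CGR, circRNA FPKM), presence/absence
# matrices, Manhattan-distance heterogeneity, hierarchical clustering and
# Pearson correlation.

#' circRNA-gene ratio (CGR)
#'
#' CGR = junction-spanning reads / host-gene reads. Returns `NA` when the
#' host gene has zero reads (undefined quotient).
#'
#' @param junction_reads non-negative integer vector.
#' @param host_reads non-negative integer vector.
#' @return numeric vector of ratios (NA where `host_reads == 0`).
#' @export
compute_cgr <- function(junction_reads, host_reads) {
  if (any(junction_reads < 0, na.rm = TRUE) ||
      any(host_reads < 0, na.rm = TRUE))
    stop("compute_cgr: inputs must be non-negative")
  out <- junction_reads / host_reads
  out[!is.na(host_reads) & host_reads == 0] <- NA_real_
  out
}

#' circRNA FPKM
#'
#' circRNA FPKM = junction-spanning reads /
#' (mapped reads in millions x host-gene FPKM). The mapped-read denominator
#' is the library's total mapped reads, not only circRNA reads. Returns `NA`
#' when either denominator term is zero.
#'
#' @param junction_reads non-negative integer vector.
#' @param mapped_reads_millions total mapped reads of the library, in
#'   millions.
#' @param host_fpkm host-gene FPKM.
#' @return numeric vector (NA where a denominator term is 0).
#' @export
compute_circ_fpkm <- function(junction_reads, mapped_reads_millions,
                              host_fpkm) {
  if (any(junction_reads < 0, na.rm = TRUE) ||
      any(mapped_reads_millions < 0, na.rm = TRUE) ||
      any(host_fpkm < 0, na.rm = TRUE))
    stop("compute_circ_fpkm: inputs must be non-negative")
  denom <- mapped_reads_millions * host_fpkm
  out <- junction_reads / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Per-observation circRNA expression table
#'
#' Joins consensus circRNAs with host-gene expression and per-cell library
#' sizes and computes CGR and circRNA FPKM for every (cell, circRNA)
#' observation.
#'
#' @param consensus tibble from [intersect_calls()] with `host_gene` filled.
#' @param expression tibble from [read_expression()] (all cells).
#' @param cell_info tibble with `cell_id`, `mapped_reads_millions`.
#' @return tibble with `circ_id`, `cell_id`, `junction_reads`, `host_gene`,
#'   `host_reads`, `host_fpkm`, `mapped_reads_millions`, `cgr`, `circ_fpkm`.
#' @export
circ_expression_table <- function(consensus, expression, cell_info) {
  expr <- expression
  names(expr)[names(expr) == "read_count"] <- "host_reads"
  names(expr)[names(expr) == "fpkm"] <- "host_fpkm"
  out <- dplyr::left_join(
    consensus[, c("circ_id", "cell_id", "junction_reads", "host_gene")],
    expr, by = c("cell_id" = "cell_id", "host_gene" = "gene_id"))
  out <- dplyr::left_join(out, cell_info[, c("cell_id",
                                             "mapped_reads_millions")],
                          by = "cell_id")
  out$cgr <- compute_cgr(out$junction_reads, out$host_reads)
  out$circ_fpkm <- compute_circ_fpkm(out$junction_reads,
                                     out$mapped_reads_millions,
                                     out$host_fpkm)
  tibble::as_tibble(out)
}

#' Cells x circRNAs presence/absence matrix
#'
#' Entry (cell, circRNA) is 1 iff that cell has at least one consensus
#' junction read for that circRNA. Features are the union of circRNAs over
#' all cells (sorted); rows for cells with no circRNAs are all zero.
#'
#' @param consensus tibble from [intersect_calls()].
#' @param cells optional cell ordering (may include cells absent from
#'   `consensus`); defaults to the sorted cells present.
#' @return integer matrix (cells x circRNAs) of 0/1 with dimnames.
#' @export
presence_matrix <- function(consensus, cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(consensus$cell_id))
  feats <- sort(unique(consensus$circ_id))
  m <- matrix(0L, nrow = length(cells), ncol = length(feats),
              dimnames = list(cells, feats))
  hit <- consensus[consensus$junction_reads >= 1 &
                     consensus$cell_id %in% cells, , drop = FALSE]
  if (nrow(hit) > 0) m[cbind(hit$cell_id, hit$circ_id)] <- 1L
  m
}

#' Pairwise Manhattan distances between cells
#'
#' d(i, j) = sum over features of |m\[i, f\] - m\[j, f\]|. On a 0/1
#' presence matrix this is the number of discordant circRNAs between two
#' cells.
#'
#' @param m cells x features numeric matrix.
#' @return symmetric cells x cells matrix with zero diagonal.
#' @export
manhattan_distances <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  as.matrix(stats::dist(m, method = "manhattan"))
}

#' Agglomerative hierarchical clustering of cells
#'
#' Standard agglomerative clustering via `stats::hclust` on the chosen
#' metric; `"correlation"` uses 1 - Pearson correlation between rows and
#' `"ward"` maps to Ward's D2 criterion.
#'
#' @param m cells x features numeric matrix (>= 2 rows).
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @param metric `"manhattan"`, `"euclidean"` or `"correlation"`.
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(m, linkage = c("average", "complete", "ward"),
                                 metric = c("manhattan", "euclidean",
                                            "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) stop("hierarchical_cluster: need at least 2 rows")
  d <- switch(metric,
    manhattan = stats::dist(m, method = "manhattan"),
    euclidean = stats::dist(m, method = "euclidean"),
    correlation = stats::as.dist(1 - stats::cor(t(m))))
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @param path optional file to write the tree to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Pearson correlation with NA-pair handling
#'
#' Drops pairs where either value is NA; with `pairing = "log10"` also drops
#' non-positive pairs and correlates the log10 values (expression quantities
#' are heavy-tailed). The p-value is the two-sided t-test of `cor.test`.
#'
#' @param x,y numeric vectors of equal length.
#' @param pairing `"raw"` (default) or `"log10"`.
#' @return list with `r`, `p`, `n` (pairs used).
#' @export
pearson_correlation <- function(x, y, pairing = c("raw", "log10")) {
  pairing <- match.arg(pairing)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (pairing == "log10") keep <- keep & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (pairing == "log10") { x <- log10(x); y <- log10(y) }
  if (length(x) < 3)
    stop("pearson_correlation: need >= 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' t-test on per-cell circRNA counts
#'
#' Convenience wrapper used to ask whether per-cell circRNA richness differs
#' from a reference value (one-sample) or between two groups of cells.
#'
#' @param m presence matrix from [presence_matrix()].
#' @param groups optional factor/vector over cells defining two groups; when
#'   `NULL` a one-sample test against `mu` is run.
#' @param mu null mean for the one-sample test.
#' @return `htest` object from [stats::t.test()].
#' @export
circ_count_t_test <- function(m, groups = NULL, mu = 0) {
  counts <- rowSums(m)
  if (is.null(groups)) return(stats::t.test(counts, mu = mu))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must define exactly 2 groups")
  stats::t.test(counts ~ groups)
}
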