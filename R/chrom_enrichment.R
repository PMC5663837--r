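# Chromosome-level feature densities (circRNA-Freq, SNP-Freq) and a
# length-proportional enrichment test.

#' circRNA frequency on a chromosome
#'
#' circRNA-Freq = 10^8 x (circRNA count on the chromosome) / (chromosome
#' length in bp). The 10^8 scale puts typical values on a comparable range
#' across chromosomes.
#'
#' @param count non-negative feature count (vectorized).
#' @param chrom_length chromosome length in bp (> 0).
#' @return numeric vector.
#' @export
circrna_freq <- function(count, chrom_length) {
  if (any(chrom_length <= 0)) stop("chrom_length must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  1e8 * count / chrom_length
}

#' SNP frequency on a chromosome
#'
#' SNP-Freq = 10^6 x (SNP count on the chromosome) / (chromosome length in
#' bp).
#'
#' @inheritParams circrna_freq
#' @return numeric vector.
#' @export
snp_freq <- function(count, chrom_length) {
  if (any(chrom_length <= 0)) stop("chrom_length must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  1e6 * count / chrom_length
}

#' Count features per chromosome
#'
#' @param tbl tibble with a `chrom` column (e.g. consensus circRNAs or
#'   filtered SNPs).
#' @param distinct_cols optional columns defining distinct features (e.g.
#'   `"circ_id"` to count cohort-level circRNAs once).
#' @return tibble with `chrom`, `count`.
#' @export
count_per_chrom <- function(tbl, distinct_cols = NULL) {
  if (!is.null(distinct_cols))
    tbl <- tbl[!duplicated(tbl[, c("chrom", distinct_cols), drop = FALSE]), ,
               drop = FALSE]
  out <- as.data.frame(table(tbl$chrom), stringsAsFactors = FALSE)
  names(out) <- c("chrom", "count")
  tibble::as_tibble(out)
}

#' Chromosome-level enrichment of feature counts
#'
#' Under uniform placement by length, the expected count on chromosome c is
#' N x length_c / sum(lengths). The default test is a one-sided exact
#' binomial for an excess of features (counts per chromosome are small);
#' `"chisq"` uses the one-sided normal score test. q-values are
#' Benjamini-Hochberg across chromosomes. Chromosomes with no observed
#' feature (e.g. chrY) are retained with count 0 and frequency 0.
#'
#' @param counts tibble with `chrom`, `count` (see [count_per_chrom()]) or a
#'   named vector.
#' @param chrom_info tibble with `chrom`, `length` from
#'   [read_chrom_info()].
#' @param test `"binomial"` (default) or `"chisq"`.
#' @param scale `"circ"` (frequency scale 10^8) or `"snp"` (10^6).
#' @param cell_id optional label carried through to the output.
#' @return tibble with `cell_id`, `chrom`, `count`, `chrom_length`, `freq`,
#'   `expected_count`, `p_value`, `q_value`.
#' @export
chromosome_enrichment <- function(counts, chrom_info,
                                  test = c("binomial", "chisq"),
                                  scale = c("circ", "snp"),
                                  cell_id = NA_character_) {
  test <- match.arg(test)
  scale <- match.arg(scale)
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(chrom = names(counts),
                             count = as.integer(counts))
  }
  if (nrow(chrom_info) < 2)
    stop("chromosome_enrichment: need at least 2 chromosomes")
  unknown <- setdiff(counts$chrom, chrom_info$chrom)
  if (length(unknown) > 0)
    stop(sprintf("counts on chromosome(s) without a length entry: %s",
                 paste(unknown, collapse = ", ")))
  cnt <- stats::setNames(rep(0L, nrow(chrom_info)), chrom_info$chrom)
  cnt[counts$chrom] <- as.integer(counts$count)
  N <- sum(cnt)
  if (N < 1) stop("chromosome_enrichment: total feature count must be >= 1")
  p0 <- chrom_info$length / sum(as.numeric(chrom_info$length))
  pv <- vapply(seq_along(cnt), function(i) {
    if (test == "binomial") {
      stats::binom.test(cnt[i], N, p = p0[i],
                        alternative = "greater")$p.value
    } else {
      se <- sqrt(N * p0[i] * (1 - p0[i]))
      stats::pnorm((cnt[i] - N * p0[i]) / se, lower.tail = FALSE)
    }
  }, numeric(1))
  freq_fun <- if (scale == "circ") circrna_freq else snp_freq
  tibble::tibble(
    cell_id = cell_id,
    chrom = chrom_info$chrom,
    count = as.integer(unname(cnt)),
    chrom_length = chrom_info$length,
    freq = unname(freq_fun(cnt, chrom_info$length)),
    expected_count = N * p0,
    p_value = pv,
    q_value = stats::p.adjust(pv, method = "BH")
  )
}

#' Heatmap-ready cells x chromosomes frequency table
#'
#' Pivots per-cell chromosome profiles to a cells x chromosomes matrix of
#' frequencies, optionally z-scores columns (zero-variance columns map to 0)
#' and orders rows/columns by hierarchical clustering (skipped when a
#' dimension has fewer than 2 entries).
#'
#' @param profiles tibble with `cell_id`, `chrom`, `freq` (rows from
#'   [chromosome_enrichment()], one call per cell).
#' @param zscore z-score columns before clustering.
#' @param cluster reorder rows and columns by average-linkage euclidean
#'   clustering.
#' @return matrix with attributes `row_order` and `col_order`.
#' @export
freq_heatmap_table <- function(profiles, zscore = FALSE, cluster = TRUE) {
  cells <- sort(unique(profiles$cell_id))
  chroms <- unique(profiles$chrom)
  m <- matrix(0, nrow = length(cells), ncol = length(chroms),
              dimnames = list(cells, chroms))
  m[cbind(profiles$cell_id, profiles$chrom)] <- profiles$freq
  if (zscore) {
    m <- apply(m, 2, function(col) {
      s <- stats::sd(col)
      if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    m <- matrix(m, nrow = length(cells), dimnames = list(cells, chroms))
  }
  row_order <- seq_len(nrow(m))
  col_order <- seq_len(ncol(m))
  if (cluster && nrow(m) >= 2)
    row_order <- hierarchical_cluster(m, "average", "euclidean")$order
  if (cluster && ncol(m) >= 2)
    col_order <- hierarchical_cluster(t(m), "average", "euclidean")$order
  out <- m[row_order, col_order, drop = FALSE]
  attr(out, "row_order") <- rownames(m)[row_order]
  attr(out, "col_order") <- colnames(m)[col_order]
  out
}
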