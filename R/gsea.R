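# Ranked-list enrichment of circRNA host genes: running-sum enrichment
# score (maximum deviation from zero) with a gene-label permutation null.

#' Construct a ranked gene list
#'
#' Orders genes by decreasing metric; ties are broken by a stable sort on
#' gene id so the ranking (and hence the enrichment score) is deterministic.
#'
#' @param genes character vector of gene ids (unique).
#' @param metric per-gene ranking metric (FPKM, SNP count, miRNA-site
#'   count, ...).
#' @param query_set gene ids of interest (circRNA host genes); only members
#'   present in `genes` count as hits.
#' @return object of class `ranked_gene_list`: list with `gene` (ordered),
#'   `metric` (non-increasing) and `query_set`.
#' @export
ranked_gene_list <- function(genes, metric, query_set) {
  stopifnot(length(genes) == length(metric))
  if (anyDuplicated(genes)) stop("ranked_gene_list: duplicate gene ids")
  ord <- order(-metric, genes)
  out <- list(gene = as.character(genes)[ord], metric = as.numeric(metric)[ord],
              query_set = unique(as.character(query_set)))
  class(out) <- "ranked_gene_list"
  out
}

#' Running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: at a query-set gene ("hit") the
#' running sum increases by w_g / sum(w over hits) where w_g = 1 for
#' `weight_p = 0` and w_g = |metric_g| for `weight_p = 1`; at a miss it
#' decreases by 1/(N - N_hits). The enrichment score (ES) is the signed
#' value of the running sum at its maximum absolute deviation from zero; an
#' exact magnitude tie between the positive and negative extremes resolves
#' to the positive one.
#'
#' @param ranked a `ranked_gene_list`.
#' @param weight_p 0 (unweighted) or 1 (weight hits by |metric|; default, as
#'   hit magnitude should track the ranking metric).
#' @return object of class `enrichment_result`: list with `es`,
#'   `running_sum`, `hit_positions`, `weight_p`, `n`, `n_hits`.
#' @export
enrichment_score <- function(ranked, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"), weight_p %in% c(0, 1))
  N <- length(ranked$gene)
  if (N < 2) stop("enrichment_score: list length must be >= 2")
  hit <- ranked$gene %in% ranked$query_set
  Nh <- sum(hit)
  if (Nh == 0) stop("enrichment_score: query set shares no gene with the list")
  if (Nh == N) stop("enrichment_score: query set equals the full list")
  res <- running_sum_walk(hit, ranked$metric, weight_p)
  out <- list(es = res$es, running_sum = res$run, hit_positions = which(hit),
              weight_p = weight_p, n = N, n_hits = Nh,
              perm_p = NA_real_, n_perm = 0L)
  class(out) <- "enrichment_result"
  out
}

# Core walk, shared with the permutation null.
running_sum_walk <- function(hit, metric, weight_p) {
  N <- length(hit)
  Nh <- sum(hit)
  w <- if (weight_p == 0) rep(1, N) else abs(metric)
  denom <- sum(w[hit])
  if (denom == 0) stop("enrichment_score: all hit weights are zero")
  step <- numeric(N)
  step[hit] <- w[hit] / denom
  step[!hit] <- -1 / (N - Nh)
  run <- cumsum(step)
  mx <- max(run)
  mn <- min(run)
  # maximum deviation from zero; an exact magnitude tie between the
  # positive and negative extremes resolves to the positive one
  es <- if (abs(mx + mn) < 1e-9 || mx + mn > 0) mx else mn
  list(es = es, run = run)
}

#' Permutation p-value for an enrichment score
#'
#' Permutes query-set membership over gene labels (the ranking metric stays
#' attached to its position), recomputes the ES for each permutation and
#' reports perm_p = (1 + #\{|ES*| >= |ES|\}) / (1 + n_perm); the +1
#' pseudo-count avoids zero p-values.
#'
#' @param ranked a `ranked_gene_list`.
#' @param n_perm number of permutations (>= 100).
#' @param weight_p see [enrichment_score()].
#' @param seed integer seed; results are reproducible given the seed and the
#'   global RNG state is left untouched.
#' @return an `enrichment_result` with `perm_p` and `n_perm` filled in.
#' @export
permutation_p <- function(ranked, n_perm = 1000, weight_p = 1, seed = 1) {
  if (n_perm < 100) stop("permutation_p: n_perm must be >= 100")
  obs <- enrichment_score(ranked, weight_p = weight_p)
  N <- obs$n
  Nh <- obs$n_hits
  metric <- ranked$metric
  stat <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hit <- logical(N)
    hit[sample.int(N, Nh)] <- TRUE
    running_sum_walk(hit, metric, weight_p)$es
  }, numeric(1)))
  obs$perm_p <- (1 + sum(abs(stat) >= abs(obs$es))) / (1 + n_perm)
  obs$n_perm <- as.integer(n_perm)
  obs
}

#' The three ranked lists of the host-gene enrichment analysis
#'
#' Builds ranked lists of (1) expressed genes ranked by FPKM, (2) genes with
#' at least one filtered SNP ranked by SNP count, and (3) genes with at
#' least one miRNA target site ranked by site count; in each list the query
#' set is the circRNA host genes present in that list.
#'
#' @param gene_fpkm tibble with `gene_id`, `fpkm` (one row per gene; e.g.
#'   mean FPKM across cells).
#' @param gene_snp_counts tibble with `gene_id`, `n_snps`.
#' @param gene_mirna_sites tibble with `gene_id`, `n_sites`.
#' @param host_genes character vector of circRNA host genes.
#' @return named list of three `ranked_gene_list` objects: `expression`,
#'   `snp`, `mirna`.
#' @export
build_ranked_lists <- function(gene_fpkm, gene_snp_counts, gene_mirna_sites,
                               host_genes) {
  host_genes <- unique(host_genes[!is.na(host_genes)])
  make <- function(df, col) {
    df <- df[!is.na(df[[col]]) & df[[col]] > 0, , drop = FALSE]
    ranked_gene_list(df$gene_id, df[[col]],
                     intersect(host_genes, df$gene_id))
  }
  list(expression = make(gene_fpkm, "fpkm"),
       snp = make(gene_snp_counts, "n_snps"),
       mirna = make(gene_mirna_sites, "n_sites"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment result: ES = %.4f (N = %d, hits = %d, weight_p = %d)\n",
    x$es, x$n, x$n_hits, x$weight_p))
  if (x$n_perm > 0)
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$perm_p, x$n_perm))
  invisible(x)
}
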