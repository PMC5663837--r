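# Config-driven end-to-end orchestration: ingest -> consensus -> quantify ->
# chromosome enrichment -> ranked-list enrichment -> sponge network ->
# report bundle (TSVs + JSON summary). Deterministic given the seed.

#' Pipeline run configuration
#'
#' Collects input locations and stage parameters. Input paths follow the
#' layout written by [simulate_cohort()] / [write_fixture_cohort()]:
#' `calls_dir/<cell>.<tool>.tsv`, `vcf_dir/<cell>.<caller>.vcf`,
#' `expression_dir/<cell>.tsv`.
#'
#' @param paths named list with `calls_dir`, `expression_dir`, `cells_file`,
#'   `chrom_sizes`, `gtf` and optionally `vcf_dir`, `mirna_fasta`,
#'   `circ_fasta`, `mirna_gene_table`, `gene_mirna_sites`,
#'   `gene_term_table`.
#' @param out_dir output directory for the report bundle.
#' @param tools required detector tools (consensus intersection set).
#' @param match_mode,window_bp junction matching (see [intersect_calls()]).
#' @param snp_thresholds hard-filter thresholds
#'   ([snp_filter_thresholds()]).
#' @param gsea_n_perm,gsea_weight_p ranked-list enrichment settings.
#' @param min_class minimum seed-match class for the sponge scan.
#' @param seed integer seed driving every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(paths, out_dir,
                       tools = TOOL_PRIORITY,
                       match_mode = "exact", window_bp = 2L,
                       snp_thresholds = snp_filter_thresholds(),
                       gsea_n_perm = 1000L, gsea_weight_p = 1,
                       min_class = "7mer-m8", seed = 1L) {
  cfg <- list(paths = paths, out_dir = out_dir, tools = tools,
              match_mode = match_mode, window_bp = as.integer(window_bp),
              snp_thresholds = snp_thresholds,
              gsea_n_perm = as.integer(gsea_n_perm),
              gsea_weight_p = gsea_weight_p, min_class = min_class,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced path exists and that each required tool has
#' at least one call file; the error names the offending tool or file.
#'
#' @param cfg a `run_config`.
#' @return the cell ids of the cohort, invisibly.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$paths
  for (key in c("calls_dir", "expression_dir", "cells_file", "chrom_sizes",
                "gtf")) {
    if (is.null(p[[key]]) || !file.exists(p[[key]]))
      stop(sprintf("run_config: required input '%s' missing (%s)", key,
                   if (is.null(p[[key]])) "not set" else p[[key]]))
  }
  cells <- utils::read.table(p$cells_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)$cell_id
  for (tool in cfg$tools) {
    for (cell in cells) {
      f <- file.path(p$calls_dir, sprintf("%s.%s.tsv", cell, tool))
      if (!file.exists(f))
        stop(sprintf("run_config: no call file for required tool '%s' (cell %s): %s",
                     tool, cell, f))
    }
  }
  invisible(cells)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

count_snps_per_gene <- function(snps, gene_index) {
  if (nrow(snps) == 0)
    return(tibble::tibble(gene_id = character(), n_snps = integer()))
  loci <- snps[!duplicated(snps[, c("chrom", "pos", "ref", "alt")]), ,
               drop = FALSE]
  q <- GenomicRanges::GRanges(loci$chrom,
                              IRanges::IRanges(loci$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, gene_index, ignore.strand = TRUE)
  gid <- as.character(gene_index$gene_id)[S4Vectors::subjectHits(hits)]
  out <- as.data.frame(table(gid), stringsAsFactors = FALSE)
  names(out) <- c("gene_id", "n_snps")
  tibble::as_tibble(out)
}

#' Per-GO/pathway-term host-gene counts
#'
#' The functional-annotation surface of the report: given a user-supplied
#' gene-to-term table, counts circRNA host genes per term (no enrichment
#' statistic is computed; annotation-service statistics are out of scope).
#'
#' @param gene_term_table tibble with `gene_id`, `term`.
#' @param host_genes character vector of circRNA host genes.
#' @return tibble with `term`, `n_host_genes`, sorted decreasing.
#' @export
term_host_gene_counts <- function(gene_term_table, host_genes) {
  tab <- gene_term_table[gene_term_table$gene_id %in% host_genes, ,
                         drop = FALSE]
  tab <- tab[!duplicated(tab[, c("gene_id", "term")]), , drop = FALSE]
  out <- as.data.frame(table(tab$term), stringsAsFactors = FALSE)
  names(out) <- c("term", "n_host_genes")
  out <- out[order(-out$n_host_genes, out$term), , drop = FALSE]
  tibble::as_tibble(out)
}

gsea_or_na <- function(ranked, n_perm, weight_p, seed) {
  tryCatch({
    res <- permutation_p(ranked, n_perm = n_perm, weight_p = weight_p,
                         seed = seed)
    list(es = res$es, perm_p = res$perm_p, n = res$n, n_hits = res$n_hits)
  }, error = function(e)
    list(es = NA, perm_p = NA, n = length(ranked$gene),
         n_hits = length(intersect(ranked$query_set, ranked$gene)),
         note = conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes a report bundle
#' under `cfg$out_dir`: consensus table, presence matrix, Manhattan
#' distances, dendrogram (Newick), chromosome enrichment tables (circRNA
#' and, when VCFs are configured, SNP), per-observation circRNA expression,
#' ranked-list enrichment running sums, sponge network (SIF + GraphML) and
#' a JSON summary. A rerun with the same config and inputs is
#' byte-identical (no timestamps in outputs).
#'
#' @param cfg a `run_config`.
#' @return invisibly, the summary list (same content as `summary.json`).
#' @export
run_pipeline <- function(cfg) {
  cells <- validate_run_config(cfg)
  p <- cfg$paths
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_stage <- function(name, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", name, n_in, n_out))
  tsv <- function(x, f) utils::write.table(
    x, out(f), sep = "\t", quote = FALSE, row.names = FALSE)

  chrom_info <- stage("ingest", read_chrom_info(p$chrom_sizes))
  gene_index <- stage("ingest", read_gtf_gene_index(p$gtf))
  cell_info <- stage("ingest", tibble::as_tibble(
    utils::read.table(p$cells_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)))

  calls <- stage("ingest", dplyr::bind_rows(lapply(cells, function(cell)
    dplyr::bind_rows(lapply(cfg$tools, function(tool)
      read_circ_calls(file.path(p$calls_dir,
                                sprintf("%s.%s.tsv", cell, tool)),
                      tool, cell))))))

  consensus <- stage("consensus",
    intersect_calls(calls, required_tools = cfg$tools,
                    match_mode = cfg$match_mode, window_bp = cfg$window_bp))
  consensus <- stage("consensus", assign_host_genes(consensus, gene_index))
  log_stage("consensus", nrow(calls), nrow(consensus))
  tsv(consensus, "consensus.tsv")

  pm <- stage("heterogeneity", presence_matrix(consensus, cells = cells))
  md <- stage("heterogeneity", manhattan_distances(pm))
  tsv(cbind(cell_id = rownames(pm), as.data.frame(pm)),
      "presence_matrix.tsv")
  tsv(cbind(cell_id = rownames(md), as.data.frame(md)), "manhattan.tsv")
  if (nrow(pm) >= 2)
    dendrogram_newick(hierarchical_cluster(pm, "complete", "manhattan"),
                      out("cells_dendrogram.nwk"))

  circ_counts <- stage("chrom_enrichment", count_per_chrom(
    consensus, distinct_cols = "circ_id"))
  circ_enrich <- stage("chrom_enrichment", chromosome_enrichment(
    circ_counts, chrom_info, test = "binomial", scale = "circ"))
  tsv(circ_enrich, "chrom_circ_enrichment.tsv")
  per_cell_circ <- stage("chrom_enrichment", dplyr::bind_rows(
    lapply(cells, function(cell) {
      sub <- consensus[consensus$cell_id == cell, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      chromosome_enrichment(count_per_chrom(sub), chrom_info,
                            scale = "circ", cell_id = cell)
    })))
  heat <- stage("chrom_enrichment", freq_heatmap_table(
    per_cell_circ, zscore = TRUE, cluster = nrow(cell_info) >= 2))
  tsv(cbind(cell_id = rownames(heat), as.data.frame(heat)),
      "chrom_circ_freq_heatmap.tsv")

  snps <- NULL
  snp_enrich <- NULL
  gene_snps <- tibble::tibble(gene_id = character(), n_snps = integer())
  if (!is.null(p$vcf_dir) && dir.exists(p$vcf_dir)) {
    raw_snps <- stage("snp_filter", dplyr::bind_rows(lapply(cells,
      function(cell) dplyr::bind_rows(lapply(c("gatk", "samtools"),
        function(caller) {
          f <- file.path(p$vcf_dir, sprintf("%s.%s.vcf", cell, caller))
          if (file.exists(f))
            suppressMessages(read_vcf(f, caller, cell)) else NULL
        })))))
    snps <- stage("snp_filter",
                  snp_consensus_filter(raw_snps, cfg$snp_thresholds))
    log_stage("snp_filter", nrow(raw_snps), nrow(snps))
    tsv(snps, "filtered_snps.tsv")
    if (nrow(snps) > 0) {
      snp_counts <- count_per_chrom(snps,
                                    distinct_cols = c("pos", "ref", "alt"))
      snp_enrich <- stage("chrom_enrichment", chromosome_enrichment(
        snp_counts, chrom_info, test = "binomial", scale = "snp"))
      tsv(snp_enrich, "chrom_snp_enrichment.tsv")
    }
    gene_snps <- stage("snp_filter", count_snps_per_gene(snps, gene_index))
  }

  expr <- stage("quantify", dplyr::bind_rows(lapply(cells, function(cell)
    read_expression(file.path(p$expression_dir, sprintf("%s.tsv", cell)),
                    cell_id = cell))))
  circ_expr <- stage("quantify",
                     circ_expression_table(consensus, expr, cell_info))
  tsv(circ_expr, "circ_expression.tsv")
  cor_safe <- function(x, y, pairing) tryCatch(
    pearson_correlation(x, y, pairing),
    error = function(e) list(r = NA, p = NA, n = 0))
  cor_cgr <- cor_safe(circ_expr$cgr, circ_expr$host_fpkm, "raw")
  cor_cgr_log <- cor_safe(circ_expr$cgr, circ_expr$host_fpkm, "log10")
  cor_cfpkm <- cor_safe(circ_expr$circ_fpkm, circ_expr$host_fpkm, "raw")
  cor_cfpkm_log <- cor_safe(circ_expr$circ_fpkm, circ_expr$host_fpkm,
                            "log10")

  host_genes <- sort(unique(consensus$host_gene[!is.na(consensus$host_gene)]))
  gene_fpkm <- expr %>% dplyr::group_by(gene_id) %>%
    dplyr::summarise(fpkm = mean(fpkm), .groups = "drop")
  gene_sites <- if (!is.null(p$gene_mirna_sites))
    tibble::as_tibble(utils::read.table(p$gene_mirna_sites, header = TRUE,
                                        sep = "\t",
                                        stringsAsFactors = FALSE))
    else tibble::tibble(gene_id = character(), n_sites = integer())
  gsea <- stage("gsea", {
    lists <- build_ranked_lists(gene_fpkm, gene_snps, gene_sites, host_genes)
    res <- list(
      expression = gsea_or_na(lists$expression, cfg$gsea_n_perm,
                              cfg$gsea_weight_p, cfg$seed + 1L),
      snp = gsea_or_na(lists$snp, cfg$gsea_n_perm, cfg$gsea_weight_p,
                       cfg$seed + 2L),
      mirna = gsea_or_na(lists$mirna, cfg$gsea_n_perm, cfg$gsea_weight_p,
                         cfg$seed + 3L))
    for (nm in names(lists)) {
      rs <- tryCatch(enrichment_score(lists[[nm]], cfg$gsea_weight_p),
                     error = function(e) NULL)
      if (!is.null(rs))
        tsv(tibble::tibble(rank = seq_along(rs$running_sum),
                           gene = lists[[nm]]$gene,
                           metric = lists[[nm]]$metric,
                           hit = seq_along(rs$running_sum) %in%
                             rs$hit_positions,
                           running_sum = rs$running_sum),
            sprintf("gsea_%s_running_sum.tsv", nm))
    }
    res
  })

  network_summary <- NULL
  top_reg <- NULL
  if (!is.null(p$mirna_fasta) && !is.null(p$circ_fasta)) {
    sponge <- stage("sponge", {
      mirnas <- read_mirnas(p$mirna_fasta)
      circ_seqs <- read_fasta(p$circ_fasta, alphabet = "DNA")
      matches <- scan_seed_sites_circular(circ_seqs, mirnas, cfg$min_class)
      tsv(matches, "seed_matches.tsv")
      mg <- if (!is.null(p$mirna_gene_table))
        tibble::as_tibble(utils::read.table(p$mirna_gene_table,
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE))
        else tibble::tibble(mirna_id = character(), gene_id = character())
      g <- build_sponge_network(matches, mg)
      write_network(g, out("sponge_network.sif"), "sif")
      write_network(g, out("sponge_network.graphml"), "graphml")
      tr <- top_regulator_mirnas(matches, k = 10)
      tsv(tr, "top_regulator_mirnas.tsv")
      vt <- igraph::vertex_attr(g, "type")
      list(summary = list(
             n_circ_nodes = sum(vt == "circRNA"),
             n_mirna_nodes = sum(vt == "miRNA"),
             n_gene_nodes = sum(vt == "gene"),
             n_edges = igraph::ecount(g)),
           top = tr)
    })
    network_summary <- sponge$summary
    top_reg <- sponge$top
  }

  if (!is.null(p$gene_term_table) && file.exists(p$gene_term_table)) {
    terms <- tibble::as_tibble(utils::read.table(p$gene_term_table,
                                                 header = TRUE, sep = "\t",
                                                 stringsAsFactors = FALSE))
    tsv(term_host_gene_counts(terms, host_genes), "term_host_gene_counts.tsv")
  }

  per_cell_counts <- as.list(stats::setNames(
    as.integer(table(factor(consensus$cell_id, levels = cells))), cells))
  summary <- list(
    n_cells = length(cells),
    consensus = list(
      per_cell = per_cell_counts,
      n_unique_circ = length(unique(consensus$circ_id)),
      n_observations = nrow(consensus)),
    heterogeneity = list(
      mean_manhattan = if (nrow(md) >= 2)
        mean(md[upper.tri(md)]) else NA),
    chromosome = list(
      circ_top_chrom = circ_enrich$chrom[which.min(circ_enrich$p_value)],
      circ_q = as.list(stats::setNames(circ_enrich$q_value,
                                       circ_enrich$chrom)),
      snp_top_chrom = if (!is.null(snp_enrich))
        snp_enrich$chrom[which.min(snp_enrich$p_value)] else NA,
      snp_q = if (!is.null(snp_enrich))
        as.list(stats::setNames(snp_enrich$q_value, snp_enrich$chrom))
        else NULL),
    n_filtered_snps = if (!is.null(snps)) nrow(snps) else NA,
    correlations = list(
      cgr_vs_host_fpkm = cor_cgr, cgr_vs_host_fpkm_log10 = cor_cgr_log,
      circ_fpkm_vs_host_fpkm = cor_cfpkm,
      circ_fpkm_vs_host_fpkm_log10 = cor_cfpkm_log),
    gsea = gsea,
    network = network_summary,
    top_regulators = if (!is.null(top_reg))
      as.list(stats::setNames(top_reg$n_circ, top_reg$mirna_id)) else NULL,
    seed = cfg$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(summary)
}
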