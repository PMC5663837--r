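#!/usr/bin/env Rscript
# Step 5: circRNA/host-gene expression coupling and host-gene ranked-list
# enrichment.
#
# Quantifies every (cell, circRNA) observation with the circRNA-gene ratio
# (CGR = junction reads / host reads) and the circRNA FPKM (junction reads
# / (mapped Mreads x host FPKM)), correlates both with host expression, and
# scores circRNA host genes in three ranked gene lists (FPKM, SNP count,
# miRNA-site count) with the running-sum enrichment statistic.

library(circkit)

cohort_dir <- "scratch/cohort"
stopifnot(file.exists("results/consensus.tsv"),
          file.exists("results/filtered_snps.tsv"))
consensus <- read.table("results/consensus.tsv", header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
cell_info <- read.table(file.path(cohort_dir, "cells.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)

expr <- dplyr::bind_rows(lapply(cell_info$cell_id, function(cell)
  read_expression(file.path(cohort_dir, "expression",
                            sprintf("%s.tsv", cell)), cell_id = cell)))
tab <- circ_expression_table(consensus, expr, cell_info)
write.table(tab, "results/circ_expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (pairing in c("raw", "log10")) {
  r1 <- pearson_correlation(tab$cgr, tab$host_fpkm, pairing)
  r2 <- pearson_correlation(tab$circ_fpkm, tab$host_fpkm, pairing)
  cat(sprintf("%s scale: PCC(CGR, host FPKM) = %.3f (p = %.3g, n = %d); ",
              pairing, r1$r, r1$p, r1$n))
  cat(sprintf("PCC(circ FPKM, host FPKM) = %.3f\n", r2$r))
}

host_genes <- sort(unique(consensus$host_gene[!is.na(consensus$host_gene)]))
gene_fpkm <- aggregate(fpkm ~ gene_id, expr, mean)
filtered <- read.table("results/filtered_snps.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
gene_index <- read_gtf_gene_index(file.path(cohort_dir, "genome",
                                            "genes.gtf"))
gene_snps <- circkit:::count_snps_per_gene(filtered, gene_index)
gene_sites <- read.table(file.path(cohort_dir, "tables",
                                   "gene_mirna_sites.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)

lists <- build_ranked_lists(gene_fpkm, gene_snps, gene_sites, host_genes)
for (nm in names(lists)) {
  res <- permutation_p(lists[[nm]], n_perm = 1000, weight_p = 1,
                       seed = 100 + match(nm, names(lists)))
  cat(sprintf("GSEA (%s list): ES = %.3f, permutation p = %.4g (N = %d, hits = %d)\n",
              nm, res$es, res$perm_p, res$n, res$n_hits))
  write.table(
    data.frame(rank = seq_along(res$running_sum),
               gene = lists[[nm]]$gene, metric = lists[[nm]]$metric,
               hit = seq_along(res$running_sum) %in% res$hit_positions,
               running_sum = res$running_sum),
    sprintf("results/gsea_%s_running_sum.tsv", nm), sep = "\t",
    quote = FALSE, row.names = FALSE)
}
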