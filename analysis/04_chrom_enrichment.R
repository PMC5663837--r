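#!/usr/bin/env Rscript
# Step 4: chromosome-level circRNA and SNP density.
#
# Normalizes cohort-level feature counts by chromosome length (circRNA-Freq
# scale 1e8, SNP-Freq scale 1e6), tests each chromosome for excess over the
# length-proportional expectation (one-sided binomial, BH-adjusted), and
# writes a z-scored heatmap table of per-cell circRNA frequencies.

library(circkit)

cohort_dir <- "scratch/cohort"
stopifnot(file.exists("results/consensus.tsv"))
consensus <- read.table("results/consensus.tsv", header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
chrom_info <- read_chrom_info(file.path(cohort_dir, "genome",
                                        "chrom_sizes.tsv"))
cells <- read.table(file.path(cohort_dir, "cells.tsv"), header = TRUE,
                    sep = "\t")$cell_id

circ_enrich <- chromosome_enrichment(
  count_per_chrom(consensus, distinct_cols = "circ_id"), chrom_info,
  test = "binomial", scale = "circ")
write.table(circ_enrich, "results/chrom_circ_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- circ_enrich[order(circ_enrich$p_value), ]
cat(sprintf("Top circRNA-enriched chromosome: %s (p = %.3g, q = %.3g)\n",
            top$chrom[1], top$p_value[1], top$q_value[1]))

per_cell <- dplyr::bind_rows(lapply(cells, function(cell) {
  sub <- consensus[consensus$cell_id == cell, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  chromosome_enrichment(count_per_chrom(sub), chrom_info, scale = "circ",
                        cell_id = cell)
}))
heat <- freq_heatmap_table(per_cell, zscore = TRUE)
write.table(cbind(cell_id = rownames(heat), as.data.frame(heat)),
            "results/chrom_circ_freq_heatmap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# SNPs: caller consensus + hard filters, then the same density test
snps <- dplyr::bind_rows(lapply(cells, function(cell)
  dplyr::bind_rows(lapply(c("gatk", "samtools"), function(caller)
    suppressMessages(read_vcf(
      file.path(cohort_dir, "vcf", sprintf("%s.%s.vcf", cell, caller)),
      caller, cell))))))
filtered <- snp_consensus_filter(snps)
write.table(filtered, "results/filtered_snps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("SNP records: %d raw -> %d after caller consensus + hard filters\n",
            nrow(snps), nrow(filtered)))
snp_enrich <- chromosome_enrichment(
  count_per_chrom(filtered, distinct_cols = c("pos", "ref", "alt")),
  chrom_info, scale = "snp")
write.table(snp_enrich, "results/chrom_snp_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
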