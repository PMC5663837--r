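#!/usr/bin/env Rscript
# Step 2: consensus circRNA calling.
#
# Reads every cell's detector outputs in all four dialects and keeps, per
# cell, the junctions reported by all four tools (exact coordinate match
# after normalization). Tool-specific decoys fall out of the intersection.

library(circkit)

cohort_dir <- "scratch/cohort"
stopifnot(dir.exists(cohort_dir))  # run 01_simulate.R first
dir.create("results", showWarnings = FALSE)

cells <- read.table(file.path(cohort_dir, "cells.tsv"), header = TRUE,
                    sep = "\t")$cell_id
tools <- c("ciri", "circexplorer", "find_circ", "circrnafinder")

calls <- dplyr::bind_rows(lapply(cells, function(cell)
  dplyr::bind_rows(lapply(tools, function(tool)
    read_circ_calls(file.path(cohort_dir, "calls",
                              sprintf("%s.%s.tsv", cell, tool)),
                    tool, cell)))))
consensus <- intersect_calls(calls, required_tools = tools)
gene_index <- read_gtf_gene_index(file.path(cohort_dir, "genome",
                                            "genes.gtf"))
consensus <- assign_host_genes(consensus, gene_index)

write.table(consensus, "results/consensus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Raw calls: %d; consensus observations: %d; unique circRNAs: %d\n",
            nrow(calls), nrow(consensus),
            length(unique(consensus$circ_id))))
cat("Per-cell consensus counts (first 10 cells):\n")
print(head(table(consensus$cell_id), 10))
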