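#!/usr/bin/env Rscript
# Step 3: cell-cell heterogeneity.
#
# Builds the cells x circRNAs presence/absence matrix, computes pairwise
# Manhattan distances (the count of discordant circRNAs between two cells)
# and clusters the cells.

library(circkit)

stopifnot(file.exists("results/consensus.tsv"))  # run 02_consensus.R first
consensus <- read.table("results/consensus.tsv", header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
cells <- read.table("scratch/cohort/cells.tsv", header = TRUE,
                    sep = "\t")$cell_id

pm <- presence_matrix(consensus, cells = cells)
md <- manhattan_distances(pm)
hc <- hierarchical_cluster(pm, linkage = "complete", metric = "manhattan")

write.table(cbind(cell_id = rownames(pm), as.data.frame(pm)),
            "results/presence_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(cell_id = rownames(md), as.data.frame(md)),
            "results/manhattan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
dendrogram_newick(hc, "results/cells_dendrogram.nwk")

cat(sprintf("Presence matrix: %d cells x %d circRNAs\n", nrow(pm), ncol(pm)))
cat(sprintf("Per-cell circRNA counts: min %d, median %.0f, max %d\n",
            min(rowSums(pm)), median(rowSums(pm)), max(rowSums(pm))))
cat(sprintf("Manhattan distance between cells: mean %.1f (range %d-%d)\n",
            mean(md[upper.tri(md)]), min(md[upper.tri(md)]),
            max(md[upper.tri(md)])))
tt <- circ_count_t_test(pm, mu = mean(rowSums(pm)))
cat(sprintf("One-sample t-test of per-cell counts vs cohort mean: p = %.3g\n",
            tt$p.value))
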