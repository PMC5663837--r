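# circkit

Single-cell circRNA profiling in R: consensus back-splice-junction calling
across detector dialects, per-cell heterogeneity statistics,
chromosome-level density enrichment, circRNA/host-gene quantification,
ranked-list enrichment of circRNA host genes, and circRNA–miRNA–mRNA
("sponge") network construction — with a ground-truth synthetic cohort
generator so the whole workflow runs and is testable without downloads.

## The problem

Circular RNAs are covalently closed transcripts created by back-splicing;
they are detected from RNA-seq reads that span the back-splice junction.
In single cells this signal is sparse and detector-dependent, so robust
profiling intersects several callers, and the biological questions are
comparative: how heterogeneous are circRNA repertoires between cells, how
does circRNA abundance relate to the host gene, where do circRNAs
concentrate in the genome, and which miRNAs could they sponge?

circkit implements that workflow for anyone analyzing per-cell circRNA
detector outputs (CIRI-style, find_circ, CIRCexplorer, circRNAFinder),
per-cell VCFs from two variant callers, and per-cell expression tables.

## Core quantities

For a circRNA with junction-spanning read count *j* in a cell whose host
gene has *R* reads and FPKM *F*, in a library with *M* million mapped
reads:

* circRNA-gene ratio: `CGR = j / R`
* circRNA FPKM: `FPKM(circ) = j / (M × F)`

Chromosome-level densities with fixed scales, for count *n* on a
chromosome of length *L* bp:

* `circRNA-Freq = 1e8 × n / L` and `SNP-Freq = 1e6 × n / L`,

tested against the length-proportional expectation with a one-sided
binomial and BH correction. SNP calls pass a caller consensus
(GATK ∩ Samtools) plus hard filters (drop QUAL < 30, QD < 20.0, DP < 8,
FS > 30.0). Host-gene enrichment in a ranked gene list uses a running-sum
enrichment score (ES): +w_g/Σw at query genes, −1/(N−N_hits) otherwise,
ES = maximum deviation from zero, with a gene-label permutation p-value.
miRNA target sites on circRNA sequences are reverse-complement seed
matches (6mer / 7mer-A1 / 7mer-m8 / 8mer), including sites that wrap the
back-splice junction.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic cohort (38 cells, 410 circRNAs, hg19 chromosome lengths,
chr22-enriched placement, a planted high-degree sponge miRNA):

```sh
Rscript analysis/01_simulate.R         # writes scratch/cohort
Rscript analysis/02_consensus.R        # four-tool intersection
Rscript analysis/03_heterogeneity.R    # presence matrix, Manhattan, tree
Rscript analysis/04_chrom_enrichment.R # circRNA-/SNP-Freq + binomial test
Rscript analysis/05_expression_gsea.R  # CGR/FPKM, correlations, 3 GSEAs
Rscript analysis/06_sponge_network.R   # seed scan + ceRNA network
```

Output from a run (seed 1):

```
Raw calls: 11708; consensus observations: 2538; unique circRNAs: 369
Presence matrix: 38 cells x 369 circRNAs
Per-cell circRNA counts: min 50, median 66, max 83
Manhattan distance between cells: mean 98.1 (range 74-133)
Top circRNA-enriched chromosome: chr22 (p = 1.03e-14, q = 2.47e-13)
SNP records: 21200 raw -> 6424 after caller consensus + hard filters
log10 scale: PCC(CGR, host FPKM) = -0.798 (p = 0, n = 2538)
GSEA (expression list): ES = 0.849, permutation p = 0.000999
GSEA (snp list):        ES = 0.148, permutation p = 0.5944
GSEA (mirna list):      ES = 0.778, permutation p = 0.000999
Top sponge-regulator miRNA: syn-miR-001 (47 distinct circRNAs)
Network: 403 circRNA, 150 miRNA, 356 gene nodes; 2142 edges
```

Reading the numbers: tool-specific decoys are eliminated by the four-tool
intersection (2538 consensus observations are exactly the planted
junction presences); circRNA repertoires differ between cells by ~98
circRNAs on average; circRNA placement is enriched on chr22 as planted;
the log-scale circRNA/host coupling recovers the generator's −0.8; host
genes are enriched among highly expressed genes and genes rich in miRNA
sites but are randomly placed in the SNP-count ranking; and the planted
regulator tops the sponge ranking against a background of ~20.

Every stage is equally usable as a library, e.g.:

```r
library(circkit)
calls <- read_circ_calls("cell1.ciri.tsv", dialect = "ciri",
                         cell_id = "cell1")
cons  <- intersect_calls(calls, required_tools = "ciri")
compute_cgr(5L, 50L)          # 0.1
circrna_freq(10L, 5e7L)       # 20
```

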