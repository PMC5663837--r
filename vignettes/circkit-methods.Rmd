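---
title: "circkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

circkit profiles circular RNAs (circRNAs) in single-cell RNA-seq
experiments. circRNAs are covalently closed transcripts formed by
back-splicing: a downstream splice donor joins an upstream acceptor, so a
circRNA is identified by reads spanning its back-splice junction.
Detection from short reads is noisy and every detector has its own
false-positive profile, which is why the field's standard practice —
followed here — is to call circRNAs with several tools and keep the
intersection. This vignette explains each statistical component, the
parameters that matter, and the design decisions taken where the
methodology was genuinely open.

## Consensus calling across detector dialects

`read_circ_calls()` parses four detector output dialects (CIRI-style TSV;
find_circ, circRNAFinder and CIRCexplorer BED-like tables). All
coordinates are normalized to 0-based half-open (the BED convention, used
by three of the four dialects); CIRI-style 1-based inclusive coordinates
have the start decremented on input. For CIRCexplorer the reader targets
the BED-like annotated output (read number in column 13, gene name in
column 15), the variant most commonly kept from its result directory.
Chromosome names are canonicalized to the `chr` prefix.

`intersect_calls()` keeps, per cell, the junctions supported by every
required tool. Matching is exact by default; because detectors genuinely
disagree by a base or two at junction boundaries, a window mode
(default ±2 bp per endpoint) is available, anchored on a fixed tool
priority (ciri > circexplorer > find_circ > circrnafinder) that also
supplies the consensus coordinates. The consensus junction read count is
the maximum across supporting tools (a detector that fails to assign some
junction reads should not drag the abundance estimate down); a mean
summary is selectable.

Host genes are assigned from a GTF interval index: the junction's both
endpoints must fall inside a single gene's span. If several genes qualify
the tie resolves by matching strand, then longest overlap, then
lexicographically smallest gene id — a deterministic rule chosen because
no standard exists. Junctions inside no gene keep a missing host (not an
error).

## SNP caller consensus and hard filters

Single-cell variant calls are kept only when both callers (GATK-style and
Samtools-style VCFs) report the same cell, chromosome, position and
alleles; survivors then pass hard filters that drop records with
QUAL < 30, QD < 20.0, DP < 8 or FS > 30.0. Removal conditions are strict
inequalities, so a record sitting exactly on a threshold (QUAL = 30,
QD = 20, DP = 8, FS = 30) is kept. The QD < 20 rule is far more stringent
than common GATK practice (QD < 2); it is implemented as specified and is
configurable through `snp_filter_thresholds()`. When callers disagree on
annotations, the GATK record is authoritative. Indels and multi-allelic
rows are excluded before filtering (the analysis concerns SNPs only).

## Expression quantities

Two per-observation quantities summarize circRNA abundance relative to
the host gene:

* CGR (circRNA-gene ratio) = junction-spanning reads / host-gene reads;
* circRNA FPKM = junction-spanning reads /
  (mapped reads in millions × host-gene FPKM).

The mapped-read denominator is the library's total mapped reads, not only
circRNA-supporting reads. Zero denominators yield `NA` rather than an
error or an infinite value, and `NA` pairs are dropped from correlations.
`pearson_correlation()` reports the sample Pearson coefficient with the
two-sided t-test p-value; a `log10` pairing is provided (and used in the
analysis scripts) because both quantities are heavy-tailed — on raw
values a single large observation can dominate the coefficient.

## Heterogeneity

Cell-cell heterogeneity is measured on the cells × circRNAs 0/1 presence
matrix (1 = at least one consensus junction read). The Manhattan distance
between two rows is then exactly the number of discordant circRNAs — an
interpretable dissimilarity for sparse binary profiles. Clustering uses
standard agglomerative methods (`stats::hclust`) on Manhattan, Euclidean
or correlation dissimilarities. Tie handling at equal merge heights
follows `hclust`'s deterministic behavior for a fixed input order; we do
not re-implement agglomeration to impose a lexicographic tie-break, since
the tree topology is what downstream consumers use and it is stable under
input-order permutation.

## Chromosome-level density and enrichment

Feature densities are chromosome-length-normalized with fixed scale
factors: circRNA-Freq = 1e8 × count / length and SNP-Freq = 1e6 × count /
length, putting typical values on a readable range. For enrichment the
null is uniform placement by length: chromosome c expects
N × length_c / Σ lengths features. Because per-cell counts are small, the
default test is the one-sided exact binomial for an excess (a chi-square
score test is available); q-values are Benjamini–Hochberg across
chromosomes. Chromosomes with zero observations (typically chrY) are
retained with frequency 0. In heatmap tables, z-scoring maps
zero-variance columns to 0 rather than `NA` so downstream clustering is
well-defined.

## Ranked-list enrichment of host genes

Whether circRNA host genes concentrate at the top of a ranked gene list
is scored with a running-sum statistic: walking the list from top to
bottom, the sum rises by w_g / Σ_hits w at each query-set gene and falls
by 1/(N − N_hits) at each miss; the enrichment score (ES) is the signed
value of the maximum deviation from zero (an exact magnitude tie between
the positive and negative extremes resolves to the positive side). With
w_g = 1 (`weight_p = 0`) the walk ends exactly at zero and is bounded by
±1; the default `weight_p = 1` weights hits by |metric|, so hit magnitude
tracks the ranking metric. Three lists are built: expressed genes ranked
by FPKM, genes with at least one filtered SNP ranked by SNP count, and
genes with at least one miRNA site ranked by site count; the query set is
the circRNA host genes present in each list. Ties in the metric break by
a stable sort on gene id so the ES is deterministic.

Significance comes from a permutation null that permutes query-set
membership over gene labels — there is no phenotype axis in this design,
so gene-set permutation is the appropriate null. The estimator
perm_p = (1 + #{|ES*| ≥ |ES|}) / (1 + n_perm) carries a +1 pseudo-count to
avoid zero p-values; it is therefore very slightly conservative, which
the null-calibration test takes into account.

## miRNA seed matching and the sponge network

Target sites on circRNA sequences are reverse-complement matches of the
miRNA seed, graded by the canonical classes: 6mer (miRNA positions 2–7),
7mer-A1 (2–7 plus an A opposite position 1), 7mer-m8 (2–8) and 8mer (2–8
plus A1); the default reporting threshold is 7mer-m8. G:U wobble pairs
are not accepted (stricter and deterministic), sequences are scanned in
sense orientation only (the mature circRNA is single-stranded), and `N`
positions never match. Because circRNAs are closed loops, a site can span
the end→start junction of the linearized sequence:
`circ_junction_site_scan()` scans the sequence extended by its first
7 nt and reports junction-crossing sites in modular coordinates, so the
full circular site set is rotation-invariant.

The sponge (ceRNA) network is a tripartite graph — circRNA→miRNA edges
from seed matches, miRNA→gene edges from a user-supplied association
table standing in for database downloads — exported as SIF or GraphML for
Cytoscape. Duplicate edges collapse with a multiplicity attribute.
`top_regulator_mirnas()` ranks miRNAs by the number of distinct circRNAs
they match, the degree notion behind "this family regulates the largest
number of circRNAs".

## The synthetic cohort

`simulate_cohort()` generates a complete cohort with known ground truth
so every stage is testable without downloads. Defaults are the study
conditions the package targets: 38 cells, 410 circRNAs placed on hg19
chromosome lengths with a 5-fold density inflation on chr22, and a target
Pearson correlation of −0.8 between log10 CGR and log10 host FPKM.
Quantities the design leaves open were fixed once at values realistic for
single-cell circRNA data and are documented here:

* per-circRNA presence probabilities ~ Beta(1.2, 6) (mean ≈ 0.17, giving
  ≈ 65 circRNAs per cell with strong cell-to-cell variability);
* log10 host FPKM ~ Normal(1.2, 0.6) for host genes and Normal(0.8, 0.6)
  for background genes (host genes sit higher, the expression pattern the
  enrichment analysis should detect), 10% of background genes silent;
* log10 CGR ~ Normal(−1.3, 0.45) coupled to the host's log FPKM through a
  bivariate-normal construction, so the target correlation holds exactly
  in the sampling distribution; junction reads = round(CGR × host reads),
  making the CGR formula invert up to rounding;
* per-tool decoy calls at rate 0.15 per true call (tool-specific, so the
  four-tool intersection removes them); optional per-tool coordinate
  jitter for exercising window matching;
* cohort SNP loci ~ Poisson(0.4) per gene, each seen per cell with
  probability 0.6; 30% of records draw exactly one annotation in its
  failing range (independent uniform marginals straddling each
  threshold — correlated failure modes are out of scope), plus
  caller-unique decoys at rate 0.15;
* 150 mature miRNAs of 22 nt; one planted regulator seeded into 40
  circRNA sequences at 7mer-m8. Random 300–600 nt backgrounds produce
  chance 7-mer matches at ≈ 4^-7 per position (about 8–11 distinct
  circRNAs per miRNA cohort-wide), so the planted degree is set well
  above that background; in small controlled panels a plant of 10 against
  ≤ 3 suffices, and the unit tests use both regimes;
* gene ids are assigned in random order so lexicographic tie-breaking
  downstream carries no information about host status;
* per-gene miRNA-site counts ~ Poisson(8) for hosts vs Poisson(3) for
  background (the site-count enrichment the miRNA ranked list should
  find).

All randomness flows from one seed through an isolated RNG state; a fixed
seed yields byte-identical files. The generator emulates the statistical
structure of real cohorts (presence heterogeneity, detector decoys,
filter-straddling annotations, negative circRNA–host coupling, planted
seed sites) but not read-level noise, splice structure, sequence
composition or correlated filter failures — so passing tests demonstrate
correct computation and parameter recovery under the stated model, not
detector behavior on real reads.

## Orchestration and determinism

`run_pipeline()` executes the full chain from a validated `run_config`
(every referenced path checked up front; a missing tool's files abort
with the tool named; stage failures abort naming the stage). Outputs are
TSV tables, SIF/GraphML networks, a Newick dendrogram and a JSON summary
with no timestamps, so reruns with the same inputs and seed are
byte-identical. The per-term host-gene count table is the only
functional-annotation surface: annotation-service statistics are out of
scope, so the report counts host genes per user-supplied term without an
enrichment claim. The numbered scripts under `analysis/` run the same
stages as a narrative workflow; `scripts/acceptance.R` recomputes the
headline quantities end to end. The test suite and the acceptance script
run the generator at reduced sizes (6–10 cells, 40–200 circRNAs) chosen
to keep the checks sharp at small cost; the acceptance script uses the
full 38 × 410 default.

## Known limitations

* The consensus window mode matches greedily from the anchor tool's
  calls; pathological call sets with several near-duplicate junctions
  within one window could double-count an anchor.
* The binomial chromosome test conditions on the total feature count and
  ignores inter-feature dependence (e.g. several circRNAs from one gene).
* Seed matching is pattern-based; no pairing thermodynamics,
  conservation, or 3'-supplementary pairing.
* The t-test utility for per-cell circRNA counts supports one-sample and
  two-group contrasts; when a published analysis reports a single t-test
  p-value without naming the contrast, neither variant can claim to
  reproduce it.
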