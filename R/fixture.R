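# A tiny in-memory cohort (3 cells, 5 circRNAs + 1 circRNA-free gene,
# 2 chromosomes, 4 miRNAs) whose every intermediate value is enumerable by
# hand. The expected_* tables ARE those hand enumerations and are asserted
# against the pipeline in the test suite.

#' Minimal hand-enumerable synthetic cohort
#'
#' Three cells, five circRNAs (one per host gene) plus one circRNA-free
#' expressed gene, two toy chromosomes and four miRNAs. Every expected
#' intermediate result ships with the fixture: the 3x5 presence matrix, the
#' 3x3 Manhattan distance table, per-observation CGR / circRNA-FPKM values,
#' cohort chromosome frequencies, the seed-match list (one planted site per
#' class, including one spanning the back-splice junction) and a 10-locus
#' SNP filter fixture with exactly 4 surviving records.
#'
#' @return a list of input tables (`cells`, `chrom_info`, `genes`, `calls`,
#'   `expression`, `snp_records`, `mirnas`, `circ_seqs`, `mirna_gene`,
#'   `gene_mirna_sites`) and hand-computed expectations (`expected_*`).
#' @export
fixture_minimal <- function() {
  cells <- tibble::tibble(
    cell_id = c("cell_1", "cell_2", "cell_3"),
    mapped_reads_millions = c(2, 4, 2.5))
  chrom_info <- tibble::tibble(chrom = c("chr1", "chr2"),
                               length = c(1000L, 500L))
  genes <- tibble::tibble(
    gene_id = paste0("gene", LETTERS[1:6]),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr1"),
    start = c(50L, 250L, 550L, 10L, 150L, 900L),
    end = c(350L, 600L, 900L, 250L, 480L, 980L),
    strand = c("+", "+", "-", "+", "-", "+"),
    length = c(300L, 350L, 350L, 240L, 330L, 80L),
    is_host = c(rep(TRUE, 5), FALSE))

  circs <- tibble::tibble(
    name = LETTERS[1:5],
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 300L, 600L, 50L, 200L),
    end = c(200L, 450L, 700L, 150L, 400L),
    strand = c("+", "+", "-", "+", "-"),
    host_gene = paste0("gene", LETTERS[1:5]))
  circs$circ_id <- circ_id_of(circs$chrom, circs$start, circs$end,
                              circs$strand)

  # presence and junction reads, per cell
  pres <- list(cell_1 = c("A", "B", "D"),
               cell_2 = c("A", "C", "D", "E"),
               cell_3 = c("B", "C"))
  jr <- list(cell_1 = c(A = 5, B = 4, D = 2),
             cell_2 = c(A = 8, C = 3, D = 6, E = 1),
             cell_3 = c(B = 10, C = 2))
  calls <- list()
  for (cell in names(pres)) {
    sub <- circs[circs$name %in% pres[[cell]], , drop = FALSE]
    for (tool in TOOL_PRIORITY) {
      calls[[length(calls) + 1L]] <- circ_call_tibble(
        cell_id = cell, chrom = sub$chrom, start = sub$start, end = sub$end,
        strand = sub$strand, junction_reads = unname(jr[[cell]][sub$name]),
        tool = tool,
        host_gene = if (tool %in% c("ciri", "circexplorer")) sub$host_gene
          else NA_character_)
    }
  }
  # one tool-specific decoy: find_circ only, cell_1 (dropped by consensus)
  calls[[length(calls) + 1L]] <- circ_call_tibble(
    cell_id = "cell_1", chrom = "chr1", start = 800L, end = 900L,
    strand = "+", junction_reads = 3L, tool = "find_circ")
  calls <- dplyr::bind_rows(calls)

  # expression: (read_count, fpkm) per cell x gene
  expression <- tibble::tibble(
    cell_id = rep(cells$cell_id, each = 6),
    gene_id = rep(genes$gene_id, 3),
    read_count = c(50L, 40L, 30L, 100L, 20L, 10L,
                   20L, 10L, 0L, 30L, 10L, 20L,
                   60L, 25L, 40L, 50L, 30L, 30L),
    fpkm = c(5, 4, 3, 10, 2, 1,
             2, 1, 0, 3, 1, 2,
             6, 2, 8, 5, 3, 3))

  # expected presence matrix / Manhattan distances (hand enumeration)
  circ_order <- sort(circs$circ_id)
  by_name <- stats::setNames(circs$circ_id, circs$name)
  expected_presence <- matrix(
    0L, nrow = 3, ncol = 5, dimnames = list(cells$cell_id, circ_order))
  for (cell in names(pres))
    expected_presence[cell, by_name[pres[[cell]]]] <- 1L
  expected_manhattan <- matrix(
    c(0, 3, 3,
      3, 0, 4,
      3, 4, 0), nrow = 3, byrow = TRUE,
    dimnames = list(cells$cell_id, cells$cell_id))

  # expected CGR / circRNA FPKM per observation (hand quotients)
  expected_circ_expression <- tibble::tibble(
    cell_id = c("cell_1", "cell_1", "cell_1",
                "cell_2", "cell_2", "cell_2", "cell_2",
                "cell_3", "cell_3"),
    name = c("A", "B", "D", "A", "C", "D", "E", "B", "C"),
    circ_id = by_name[c("A", "B", "D", "A", "C", "D", "E", "B", "C")],
    junction_reads = c(5, 4, 2, 8, 3, 6, 1, 10, 2),
    host_reads = c(50, 40, 100, 20, 0, 30, 10, 25, 40),
    host_fpkm = c(5, 4, 10, 2, 0, 3, 1, 2, 8),
    cgr = c(0.1, 0.1, 0.02, 0.4, NA, 0.2, 0.1, 0.4, 0.05),
    circ_fpkm = c(0.5, 0.5, 0.1, 1.0, NA, 0.5, 0.25, 2.0, 0.1))

  # cohort-level chromosome frequencies: 3 circRNAs on chr1 (L = 1000),
  # 2 on chr2 (L = 500)
  expected_circ_freq <- tibble::tibble(
    chrom = c("chr1", "chr2"),
    count = c(3L, 2L),
    freq = c(1e8 * 3 / 1000, 1e8 * 2 / 500))

  # miRNAs; seeds (positions 2-8) reverse-complement to the planted sites
  mirnas <- tibble::tibble(
    mirna_id = c("fx-miR-01", "fx-miR-02", "fx-miR-03", "fx-miR-04"),
    sequence = c("UAGCAGCACGUAAAUAUUGGCG",   # seed AGCAGCA -> site TGCTGCT
                 "UGAGGUAGUAGGUUGUAUAGUU",   # seed GAGGUAG -> site CTACCTC
                 "UUCACAGUGGCUAAGUUCUGC",    # seed UCACAGU -> site ACTGTGA
                 "ACGUACGUACGUACGUACGUAA"),  # seed CGUACGU -> site ACGTACG
    seed = c("AGCAGCA", "GAGGUAG", "UCACAGU", "CGUACGU"))

  # backgrounds avoid T (and CGTACG), so the planted sites are the only
  # matches; circB's site wraps the back-splice junction (split 4 + 3)
  circ_seqs <- stats::setNames(c(
    paste0("CCGGAACCGG", "TGCTGCTA", "CCGGAACCGGAACCGGAACCGG"),
    paste0("CTC", "CCGGAACCGGAACCGGAACCGGA", "CTAC"),
    paste0("CCGGC", "CTGTGAA", "GGCCGGCCGGCCGGCCGGCCGGCC"),
    paste0("CCGGCCGGCCGG", "CGTACG", "CCGGCCGGCCGG"),
    "GGCCGGCCGGCCGGCCGGCCGGCCGGCCGG"), by_name[c("A", "B", "C", "D", "E")])

  expected_seed_matches <- tibble::tibble(
    circ_id = by_name[c("A", "C", "D")],
    mirna_id = c("fx-miR-01", "fx-miR-03", "fx-miR-04"),
    site_start = c(10L, 5L, 12L),
    match_class = c("8mer", "7mer-A1", "6mer"))
  expected_junction_matches <- tibble::tibble(
    circ_id = by_name["B"],
    mirna_id = "fx-miR-02",
    site_start = 26L,
    match_class = "7mer-m8")

  # 10-locus SNP fixture: 4 pass (one at all keep-side boundaries), 4 fail
  # exactly one filter each, 2 caller-unique
  both <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(100L, 500L, 920L, 950L, 150L, 160L, 170L, 180L),
    ref = c("A", "C", "G", "T", "A", "C", "G", "T"),
    alt = c("G", "T", "A", "C", "G", "T", "A", "C"),
    qual = c(50, 30, 80, 45, 29, 50, 50, 50),
    qd = c(25, 20, 30, 22, 25, 19.9, 25, 25),
    dp = c(20L, 8L, 40L, 12L, 20L, 20L, 7L, 20L),
    fs = c(5, 30, 0, 10, 5, 5, 5, 30.1))
  snp_records <- dplyr::bind_rows(
    dplyr::mutate(both, cell_id = "cell_1", caller = "gatk"),
    dplyr::mutate(both, cell_id = "cell_1", caller = "samtools"),
    tibble::tibble(cell_id = "cell_1", chrom = "chr2", pos = 100L,
                   ref = "A", alt = "T", qual = 60, qd = 25, dp = 30L,
                   fs = 2, caller = "gatk"),
    tibble::tibble(cell_id = "cell_1", chrom = "chr2", pos = 200L,
                   ref = "C", alt = "G", qual = 60, qd = 25, dp = 30L,
                   fs = 2, caller = "samtools"))
  snp_records <- snp_records[, c("cell_id", "chrom", "pos", "ref", "alt",
                                 "qual", "qd", "dp", "fs", "caller")]
  expected_snp_survivor_pos <- c(100L, 500L, 920L, 950L)

  mirna_gene <- tibble::tibble(
    mirna_id = c("fx-miR-01", "fx-miR-01", "fx-miR-02", "fx-miR-03",
                 "fx-miR-04"),
    gene_id = c("geneA", "geneB", "geneC", "geneD", "geneE"))
  gene_mirna_sites <- tibble::tibble(
    gene_id = c("geneA", "geneB", "geneC", "geneF"),
    n_sites = c(3L, 2L, 1L, 1L))

  expected_consensus_counts <- c(cell_1 = 3L, cell_2 = 4L, cell_3 = 2L)

  list(cells = cells, chrom_info = chrom_info, genes = genes,
       circs = circs, calls = calls, expression = expression,
       snp_records = snp_records, mirnas = mirnas, circ_seqs = circ_seqs,
       mirna_gene = mirna_gene, gene_mirna_sites = gene_mirna_sites,
       expected_presence = expected_presence,
       expected_manhattan = expected_manhattan,
       expected_circ_expression = expected_circ_expression,
       expected_circ_freq = expected_circ_freq,
       expected_seed_matches = expected_seed_matches,
       expected_junction_matches = expected_junction_matches,
       expected_snp_survivor_pos = expected_snp_survivor_pos,
       expected_consensus_counts = expected_consensus_counts)
}

#' Write the minimal fixture as an on-disk cohort
#'
#' Serializes [fixture_minimal()] in the same directory layout as
#' [simulate_cohort()] so the end-to-end pipeline can run on it.
#'
#' @param fx fixture from [fixture_minimal()].
#' @param outdir output directory.
#' @return named list of input paths (as in `simulate_cohort()$paths`).
#' @export
write_fixture_cohort <- function(fx, outdir) {
  for (d in c("", "calls", "vcf", "expression", "genome", "seqs", "tables"))
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  for (cell in fx$cells$cell_id) {
    for (tool in TOOL_PRIORITY) {
      cc <- fx$calls[fx$calls$cell_id == cell & fx$calls$tool == tool, ,
                     drop = FALSE]
      write_circ_calls(cc, file.path(outdir, "calls",
                                     sprintf("%s.%s.tsv", cell, tool)), tool)
    }
    for (caller in c("gatk", "samtools")) {
      rec <- fx$snp_records[fx$snp_records$cell_id == cell &
                              fx$snp_records$caller == caller, , drop = FALSE]
      write_vcf_text(rec, file.path(outdir, "vcf",
                                    sprintf("%s.%s.vcf", cell, caller)))
    }
    expr <- fx$expression[fx$expression$cell_id == cell,
                          c("gene_id", "read_count", "fpkm"), drop = FALSE]
    utils::write.table(expr, file.path(outdir, "expression",
                                       sprintf("%s.tsv", cell)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(fx$cells, file.path(outdir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$chrom_info,
                     file.path(outdir, "genome", "chrom_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_gtf_text(fx$genes, file.path(outdir, "genome", "genes.gtf"))
  write_fasta(stats::setNames(fx$mirnas$sequence, fx$mirnas$mirna_id),
              file.path(outdir, "seqs", "mirnas.fa"))
  write_fasta(fx$circ_seqs, file.path(outdir, "seqs", "circs.fa"))
  utils::write.table(fx$mirna_gene,
                     file.path(outdir, "tables", "mirna_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$gene_mirna_sites,
                     file.path(outdir, "tables", "gene_mirna_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(
    calls_dir = file.path(outdir, "calls"),
    vcf_dir = file.path(outdir, "vcf"),
    expression_dir = file.path(outdir, "expression"),
    cells_file = file.path(outdir, "cells.tsv"),
    chrom_sizes = file.path(outdir, "genome", "chrom_sizes.tsv"),
    gtf = file.path(outdir, "genome", "genes.gtf"),
    mirna_fasta = file.path(outdir, "seqs", "mirnas.fa"),
    circ_fasta = file.path(outdir, "seqs", "circs.fa"),
    mirna_gene_table = file.path(outdir, "tables", "mirna_gene.tsv"),
    gene_mirna_sites = file.path(outdir, "tables", "gene_mirna_sites.tsv"),
    gene_term_table = NULL)
}
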