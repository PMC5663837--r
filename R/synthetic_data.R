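# Synthetic single-cell cohort generator with full ground truth: per-cell
# circRNA detector outputs in four dialects (true junctions plus
# tool-specific decoys), two-caller VCFs straddling the hard-filter
# thresholds, expression tables with a negative log-CGR/log-host-FPKM
# coupling, annotation, and miRNA/circRNA sequences with planted seed sites.

#' hg19 chromosome lengths
#'
#' The 24 nuclear chromosome lengths of the hg19 human assembly.
#'
#' @return tibble with `chrom`, `length`.
#' @export
hg19_chrom_info <- function() {
  tibble::tibble(
    chrom = paste0("chr", c(1:22, "X", "Y")),
    length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
               171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
               135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
               90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
               48129895L, 51304566L, 155270560L, 59373566L))
}

#' Configuration for the synthetic cohort
#'
#' Defaults emulate the study conditions of the cohort the package targets:
#' 38 single cells, 410 consensus circRNAs on hg19 chromosomes with a
#' 5-fold circRNA enrichment on chr22, a log-scale Pearson correlation of
#' -0.8 between CGR and host-gene FPKM, heterogeneous sparse per-cell
#' presence, hard-filter annotations straddling the QUAL/QD/DP/FS
#' thresholds, and one high-degree "sponge regulator" miRNA planted across
#' circRNA sequences.
#'
#' @param n_cells number of cells.
#' @param n_circ number of true circRNAs (one host gene each).
#' @param n_genes total genes (hosts plus background).
#' @param chrom_info tibble with `chrom`, `length`.
#' @param enriched_chrom chromosome with inflated circRNA density (`NULL`
#'   for uniform placement).
#' @param enriched_fold density fold-change on `enriched_chrom`.
#' @param presence_shape1,presence_shape2 Beta parameters for per-circRNA
#'   presence probabilities.
#' @param tool_fp_rate named (or scalar) per-tool false-positive rate:
#'   expected decoy calls per true call.
#' @param tool_jitter_bp coordinate jitter applied to non-anchor tools
#'   (0 keeps all tools exactly concordant).
#' @param cgr_host_corr target Pearson correlation between log10 CGR and
#'   log10 host FPKM (negative).
#' @param cgr_log_mean,cgr_log_sd log10-scale CGR location/spread.
#' @param host_log_fpkm_mean,bg_log_fpkm_mean,log_fpkm_sd log10-FPKM
#'   location for host/background genes and common spread.
#' @param snp_rate_per_gene expected cohort SNP loci per gene.
#' @param snp_detect_prob per-cell detection probability of a cohort locus.
#' @param snp_fail_frac fraction of records drawn to fail exactly one hard
#'   filter.
#' @param caller_fp_rate caller-unique decoy records per true record.
#' @param n_mirnas number of mature miRNAs.
#' @param n_planted_regulator circRNAs carrying a planted site of the first
#'   miRNA (the designed top sponge regulator).
#' @param planted_sites optional tibble (`circ_index`, `mirna_index`,
#'   `class`) of extra planted sites.
#' @param circ_seq_len_range length range of circRNA sequences (nt).
#' @param frac_silent_genes fraction of background genes with zero
#'   expression.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 38L,
                       n_circ = 410L,
                       n_genes = 1000L,
                       chrom_info = hg19_chrom_info(),
                       enriched_chrom = "chr22",
                       enriched_fold = 5,
                       presence_shape1 = 1.2,
                       presence_shape2 = 6,
                       tool_fp_rate = 0.15,
                       tool_jitter_bp = 0L,
                       cgr_host_corr = -0.8,
                       cgr_log_mean = -1.3,
                       cgr_log_sd = 0.45,
                       host_log_fpkm_mean = 1.2,
                       bg_log_fpkm_mean = 0.8,
                       log_fpkm_sd = 0.6,
                       snp_rate_per_gene = 0.4,
                       snp_detect_prob = 0.6,
                       snp_fail_frac = 0.3,
                       caller_fp_rate = 0.15,
                       n_mirnas = 150L,
                       n_planted_regulator = 40L,
                       planted_sites = NULL,
                       circ_seq_len_range = c(300L, 600L),
                       frac_silent_genes = 0.1,
                       seed = 1L) {
  if (length(tool_fp_rate) == 1)
    tool_fp_rate <- stats::setNames(rep(tool_fp_rate, 4), TOOL_PRIORITY)
  stopifnot(n_genes >= n_circ, abs(cgr_host_corr) < 1,
            presence_shape1 > 0, presence_shape2 > 0,
            all(tool_fp_rate >= 0), snp_fail_frac >= 0, snp_fail_frac <= 1)
  cfg <- list(
    n_cells = as.integer(n_cells), n_circ = as.integer(n_circ),
    n_genes = as.integer(n_genes), chrom_info = chrom_info,
    enriched_chrom = enriched_chrom, enriched_fold = enriched_fold,
    presence_shape1 = presence_shape1, presence_shape2 = presence_shape2,
    tool_fp_rate = tool_fp_rate, tool_jitter_bp = as.integer(tool_jitter_bp),
    cgr_host_corr = cgr_host_corr, cgr_log_mean = cgr_log_mean,
    cgr_log_sd = cgr_log_sd, host_log_fpkm_mean = host_log_fpkm_mean,
    bg_log_fpkm_mean = bg_log_fpkm_mean, log_fpkm_sd = log_fpkm_sd,
    snp_rate_per_gene = snp_rate_per_gene, snp_detect_prob = snp_detect_prob,
    snp_fail_frac = snp_fail_frac, caller_fp_rate = caller_fp_rate,
    n_mirnas = as.integer(n_mirnas),
    n_planted_regulator = as.integer(n_planted_regulator),
    planted_sites = planted_sites,
    circ_seq_len_range = as.integer(circ_seq_len_range),
    frac_silent_genes = frac_silent_genes, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sample_chrom <- function(n, chrom_info, enriched_chrom = NULL, fold = 1) {
  w <- as.numeric(chrom_info$length)
  if (!is.null(enriched_chrom)) {
    i <- match(enriched_chrom, chrom_info$chrom)
    if (is.na(i)) stop("enriched_chrom not in chrom_info")
    w[i] <- w[i] * fold
  }
  sample(chrom_info$chrom, n, replace = TRUE, prob = w / sum(w))
}

random_dna <- function(n_seq, lens) {
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

random_rna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Draws the whole cohort in memory. Called under withr::with_seed so every
# random choice flows from cfg$seed.
sim_draw <- function(cfg) {
  ci <- cfg$chrom_info
  cells <- sprintf("cell_%02d", seq_len(cfg$n_cells))
  n_host <- cfg$n_circ
  n_bg <- cfg$n_genes - n_host

  # genes: hosts placed with the enrichment fold, background by length
  gene_len <- sample(10000:100000, cfg$n_genes, replace = TRUE)
  gene_chrom <- c(
    sample_chrom(n_host, ci, cfg$enriched_chrom, cfg$enriched_fold),
    sample_chrom(n_bg, ci))
  max_start <- ci$length[match(gene_chrom, ci$chrom)] - gene_len - 1L
  gene_start <- vapply(max_start, function(m) sample.int(m, 1L), integer(1))
  # ids are assigned in random order so lexicographic tie-breaks downstream
  # carry no information about host status
  genes <- tibble::tibble(
    gene_id = sample(sprintf("G%04d", seq_len(cfg$n_genes))),
    chrom = gene_chrom,
    start = gene_start,                       # 0-based
    end = gene_start + gene_len,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    length = gene_len,
    is_host = c(rep(TRUE, n_host), rep(FALSE, n_bg)))

  # one circRNA inside each host gene span
  circ_w <- pmin(sample(200:2000, n_host, replace = TRUE),
                 gene_len[seq_len(n_host)] - 10L)
  circ_off <- vapply(gene_len[seq_len(n_host)] - circ_w, function(m)
    sample.int(m, 1L), integer(1))
  circs <- tibble::tibble(
    chrom = genes$chrom[seq_len(n_host)],
    start = genes$start[seq_len(n_host)] + circ_off,
    end = genes$start[seq_len(n_host)] + circ_off + circ_w,
    strand = genes$strand[seq_len(n_host)],
    host_gene = genes$gene_id[seq_len(n_host)],
    presence_prob = stats::rbeta(n_host, cfg$presence_shape1,
                                 cfg$presence_shape2))
  circs$circ_id <- circ_id_of(circs$chrom, circs$start, circs$end,
                              circs$strand)

  presence <- matrix(
    stats::rbinom(cfg$n_cells * n_host, 1L,
                  rep(circs$presence_prob, each = cfg$n_cells)),
    nrow = cfg$n_cells, dimnames = list(cells, circs$circ_id))

  cell_info <- tibble::tibble(
    cell_id = cells,
    mapped_reads_millions = round(stats::runif(cfg$n_cells, 2, 6), 3))

  # expression: log10 FPKM per (cell, gene); hosts sit higher than
  # background, matching the observed expression enrichment of host genes
  mu_g <- ifelse(genes$is_host, cfg$host_log_fpkm_mean,
                 cfg$bg_log_fpkm_mean)
  silent <- rep(FALSE, cfg$n_genes)
  if (n_bg > 0 && cfg$frac_silent_genes > 0) {
    idx_bg <- which(!genes$is_host)
    silent[sample(idx_bg, round(cfg$frac_silent_genes * n_bg))] <- TRUE
  }
  z1 <- matrix(stats::rnorm(cfg$n_cells * cfg$n_genes), nrow = cfg$n_cells,
               dimnames = list(cells, genes$gene_id))
  log_fpkm <- sweep(cfg$log_fpkm_sd * z1, 2, mu_g, `+`)
  fpkm <- 10^log_fpkm
  fpkm[, silent] <- 0
  glen_kb <- genes$length / 1000
  reads <- round(sweep(sweep(fpkm, 2, glen_kb, `*`), 1,
                       cell_info$mapped_reads_millions, `*`))

  # CGR coupled to host FPKM on the log scale via the bivariate-normal
  # construction: corr(log CGR, log FPKM) = cgr_host_corr exactly
  r <- cfg$cgr_host_corr
  host_idx <- match(circs$host_gene, genes$gene_id)
  obs <- which(presence == 1L, arr.ind = TRUE)
  z1_obs <- z1[cbind(obs[, 1], host_idx[obs[, 2]])]
  z2 <- stats::rnorm(nrow(obs))
  log_cgr <- cfg$cgr_log_mean +
    cfg$cgr_log_sd * (r * z1_obs + sqrt(1 - r^2) * z2)
  host_reads_obs <- reads[cbind(obs[, 1], host_idx[obs[, 2]])]
  jr <- pmax(1L, as.integer(round(10^log_cgr * host_reads_obs)))
  expr_truth <- tibble::tibble(
    cell_id = cells[obs[, 1]],
    circ_id = circs$circ_id[obs[, 2]],
    host_gene = circs$host_gene[obs[, 2]],
    log10_cgr = log_cgr,
    log10_host_fpkm = log_fpkm[cbind(obs[, 1], host_idx[obs[, 2]])],
    junction_reads = jr)

  # per-cell per-tool calls: true junctions in all four dialects plus
  # tool-specific decoys
  calls <- list()
  for (icell in seq_len(cfg$n_cells)) {
    pres <- which(presence[icell, ] == 1L)
    tr <- expr_truth[expr_truth$cell_id == cells[icell], , drop = FALSE]
    jr_map <- stats::setNames(tr$junction_reads, tr$circ_id)
    for (tool in TOOL_PRIORITY) {
      true_block <- if (length(pres) > 0) circ_call_tibble(
        cell_id = cells[icell], chrom = circs$chrom[pres],
        start = circs$start[pres], end = circs$end[pres],
        strand = circs$strand[pres],
        junction_reads = unname(jr_map[circs$circ_id[pres]]),
        tool = tool,
        host_gene = if (tool %in% c("ciri", "circexplorer"))
          circs$host_gene[pres] else NA_character_) else empty_circ_calls()
      if (cfg$tool_jitter_bp > 0 && tool != "ciri" && nrow(true_block) > 0) {
        true_block$start <- true_block$start +
          sample(-cfg$tool_jitter_bp:cfg$tool_jitter_bp, nrow(true_block),
                 replace = TRUE)
        true_block$end <- true_block$end +
          sample(-cfg$tool_jitter_bp:cfg$tool_jitter_bp, nrow(true_block),
                 replace = TRUE)
      }
      n_decoy <- stats::rpois(1, cfg$tool_fp_rate[[tool]] *
                                max(1L, length(pres)))
      decoy_block <- if (n_decoy > 0) {
        dch <- sample_chrom(n_decoy, ci)
        dw <- sample(200:2000, n_decoy, replace = TRUE)
        dst <- vapply(ci$length[match(dch, ci$chrom)] - dw - 1L,
                      function(m) sample.int(m, 1L), integer(1))
        circ_call_tibble(
          cell_id = cells[icell], chrom = dch, start = dst, end = dst + dw,
          strand = sample(c("+", "-"), n_decoy, replace = TRUE),
          junction_reads = sample(1:10, n_decoy, replace = TRUE),
          tool = tool)
      } else empty_circ_calls()
      calls[[length(calls) + 1L]] <- dplyr::bind_rows(true_block,
                                                      decoy_block)
    }
  }
  calls <- dplyr::bind_rows(calls)

  # cohort SNP loci within genes; per-cell observation with annotations
  # drawn so snp_fail_frac of records fail exactly one hard filter
  n_loci_per_gene <- stats::rpois(cfg$n_genes, cfg$snp_rate_per_gene)
  loci <- list()
  for (gi in which(n_loci_per_gene > 0)) {
    k <- n_loci_per_gene[gi]
    pos <- genes$start[gi] + sample.int(genes$length[gi], k)
    refs <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alts <- vapply(refs, function(rf)
      sample(setdiff(c("A", "C", "G", "T"), rf), 1L), character(1))
    loci[[length(loci) + 1L]] <- tibble::tibble(
      chrom = genes$chrom[gi], pos = pos, ref = refs, alt = alts,
      gene_id = genes$gene_id[gi])
  }
  loci <- if (length(loci) > 0) dplyr::bind_rows(loci) else
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), gene_id = character())
  loci <- loci[!duplicated(loci[, c("chrom", "pos")]), , drop = FALSE]

  snp_records <- list()
  for (icell in seq_len(cfg$n_cells)) {
    seen <- loci[stats::runif(nrow(loci)) < cfg$snp_detect_prob, ,
                 drop = FALSE]
    n <- nrow(seen)
    if (n > 0) {
      qual <- stats::runif(n, 30, 100)
      qd <- stats::runif(n, 20, 40)
      dp <- sample(8:60, n, replace = TRUE)
      fs <- stats::runif(n, 0, 30)
      fail <- stats::runif(n) < cfg$snp_fail_frac
      which_fail <- sample(1:4, n, replace = TRUE)
      qual[fail & which_fail == 1] <-
        stats::runif(sum(fail & which_fail == 1), 5, 29.9)
      qd[fail & which_fail == 2] <-
        stats::runif(sum(fail & which_fail == 2), 2, 19.9)
      dp[fail & which_fail == 3] <-
        sample(1:7, sum(fail & which_fail == 3), replace = TRUE)
      fs[fail & which_fail == 4] <-
        stats::runif(sum(fail & which_fail == 4), 30.1, 60)
      base <- tibble::tibble(
        cell_id = cells[icell], chrom = seen$chrom, pos = seen$pos,
        ref = seen$ref, alt = seen$alt, qual = round(qual, 2),
        qd = round(qd, 2), dp = as.integer(dp), fs = round(fs, 2),
        gene_id = seen$gene_id, passes = !fail, both_callers = TRUE)
      snp_records[[length(snp_records) + 1L]] <- base
    }
    # caller-unique decoys
    for (caller in c("gatk", "samtools")) {
      n_extra <- stats::rpois(1, cfg$caller_fp_rate * max(1L, n))
      if (n_extra > 0) {
        dch <- sample_chrom(n_extra, ci)
        dpos <- vapply(ci$length[match(dch, ci$chrom)], function(m)
          sample.int(m - 1L, 1L), integer(1))
        refs <- sample(c("A", "C", "G", "T"), n_extra, replace = TRUE)
        alts <- vapply(refs, function(rf)
          sample(setdiff(c("A", "C", "G", "T"), rf), 1L), character(1))
        snp_records[[length(snp_records) + 1L]] <- tibble::tibble(
          cell_id = cells[icell], chrom = dch, pos = dpos, ref = refs,
          alt = alts, qual = round(stats::runif(n_extra, 30, 100), 2),
          qd = round(stats::runif(n_extra, 20, 40), 2),
          dp = sample(8:60, n_extra, replace = TRUE),
          fs = round(stats::runif(n_extra, 0, 30), 2),
          gene_id = NA_character_, passes = NA,
          both_callers = FALSE, unique_to = caller)
      }
    }
  }
  snp_records <- dplyr::bind_rows(snp_records)
  if (!"unique_to" %in% names(snp_records))
    snp_records$unique_to <- NA_character_

  # sequences: mature miRNAs and circRNA sequences with planted seed sites
  mirnas <- tibble::tibble(
    mirna_id = sprintf("syn-miR-%03d", seq_len(cfg$n_mirnas)),
    sequence = random_rna(cfg$n_mirnas, 22L))
  circ_lens <- sample(cfg$circ_seq_len_range[1]:cfg$circ_seq_len_range[2],
                      n_host, replace = TRUE)
  circ_seqs <- stats::setNames(random_dna(n_host, circ_lens), circs$circ_id)

  planted <- cfg$planted_sites
  if (is.null(planted) && cfg$n_planted_regulator > 0) {
    targets <- sample(n_host, min(cfg$n_planted_regulator, n_host))
    planted <- tibble::tibble(circ_index = targets, mirna_index = 1L,
                              class = "7mer-m8")
  }
  planted_out <- list()
  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      ci_idx <- planted$circ_index[i]
      mk <- planted$mirna_index[i]
      cls <- planted$class[i]
      mseq <- chartr("U", "T", mirnas$sequence[mk])
      ins <- revcomp_dna(substr(mseq, 2, 8))
      ins <- paste0(ins, if (cls == "8mer") "A" else "C")
      s <- circ_seqs[[ci_idx]]
      off <- sample.int(nchar(s) - nchar(ins) - 1L, 1L)
      substr(s, off + 1L, off + nchar(ins)) <- ins
      circ_seqs[[ci_idx]] <- s
      planted_out[[length(planted_out) + 1L]] <- tibble::tibble(
        circ_id = circs$circ_id[ci_idx], mirna_id = mirnas$mirna_id[mk],
        site_start = off, match_class = cls)
    }
  }
  planted_sites <- if (length(planted_out) > 0) dplyr::bind_rows(planted_out)
    else empty_seed_matches()

  # association and per-gene miRNA-site-count tables; host genes carry more
  # sites, matching the observed miRNA-site enrichment of host genes
  mirna_gene <- tibble::tibble(
    mirna_id = rep(mirnas$mirna_id, each = 3),
    gene_id = unlist(lapply(seq_len(cfg$n_mirnas), function(i)
      sample(genes$gene_id, 3))))
  gene_mirna_sites <- tibble::tibble(
    gene_id = genes$gene_id,
    n_sites = stats::rpois(cfg$n_genes, ifelse(genes$is_host, 8, 3)))
  gene_terms <- tibble::tibble(
    gene_id = rep(genes$gene_id, 2),
    term = sample(sprintf("TERM:%04d", 1:12), 2 * cfg$n_genes,
                  replace = TRUE))

  list(cells = cell_info, genes = genes, circs = circs, presence = presence,
       expr_truth = expr_truth, log_fpkm = log_fpkm, fpkm = fpkm,
       reads = reads, calls = calls, snp_loci = loci,
       snp_records = snp_records, mirnas = mirnas, circ_seqs = circ_seqs,
       planted_sites = planted_sites, mirna_gene = mirna_gene,
       gene_mirna_sites = gene_mirna_sites, gene_terms = gene_terms)
}

write_vcf_text <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=circkit_synthetic_cohort",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rows <- if (nrow(records) == 0) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t%.2f\t.\tDP=%d;QD=%.2f;FS=%.2f",
    records$chrom, records$pos + 1L, records$ref, records$alt, records$qual,
    records$dp, records$qd, records$fs)
  writeLines(c(header, rows), path)
  invisible(path)
}

write_gtf_text <- function(genes, path) {
  rows <- sprintf(
    "%s\tcirckit_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id,
    genes$gene_id)
  writeLines(rows, path)
  invisible(path)
}

#' Simulate a complete synthetic single-cell cohort
#'
#' Draws the cohort of [sim_config()] and writes every pipeline input
#' format under `outdir`: per-cell per-tool circRNA call files (true
#' junctions in all four dialects plus tool-specific decoys), per-cell
#' GATK/Samtools VCFs with QUAL/QD/DP/FS annotations straddling the hard
#' filters, per-cell expression tables, chromosome sizes, a gene GTF, miRNA
#' and circRNA FASTA with planted seed sites, miRNA-gene association
#' tables, and a `truth/` directory keying every planted fact. All
#' randomness flows from `cfg$seed`; the same seed gives byte-identical
#' files.
#'
#' @param cfg a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `paths` (named input locations), `truth`
#'   (in-memory ground-truth tables) and `cfg`.
#' @export
simulate_cohort <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  for (d in c("", "calls", "vcf", "expression", "genome", "seqs", "tables",
              "truth")) {
    dd <- file.path(outdir, d)
    if (!dir.exists(dd) && !dir.create(dd, recursive = TRUE))
      stop(sprintf("cannot create output directory %s", dd))
  }
  truth <- withr::with_seed(cfg$seed, sim_draw(cfg))
  cells <- truth$cells$cell_id

  for (cell in cells) {
    for (tool in TOOL_PRIORITY) {
      cc <- truth$calls[truth$calls$cell_id == cell &
                          truth$calls$tool == tool, , drop = FALSE]
      write_circ_calls(cc, file.path(outdir, "calls",
                                     sprintf("%s.%s.tsv", cell, tool)), tool)
    }
    for (caller in c("gatk", "samtools")) {
      rec <- truth$snp_records
      rec <- rec[rec$cell_id == cell &
                   (rec$both_callers |
                      (!is.na(rec$unique_to) & rec$unique_to == caller)), ,
                 drop = FALSE]
      write_vcf_text(rec, file.path(outdir, "vcf",
                                    sprintf("%s.%s.vcf", cell, caller)))
    }
    expr <- tibble::tibble(
      gene_id = truth$genes$gene_id,
      read_count = as.integer(truth$reads[cell, ]),
      fpkm = round(truth$fpkm[cell, ], 6))
    utils::write.table(expr, file.path(outdir, "expression",
                                       sprintf("%s.tsv", cell)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(truth$cells, file.path(outdir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cfg$chrom_info, file.path(outdir, "genome",
                                               "chrom_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_gtf_text(truth$genes, file.path(outdir, "genome", "genes.gtf"))
  write_fasta(stats::setNames(truth$mirnas$sequence, truth$mirnas$mirna_id),
              file.path(outdir, "seqs", "mirnas.fa"))
  write_fasta(truth$circ_seqs, file.path(outdir, "seqs", "circs.fa"))
  utils::write.table(truth$mirna_gene, file.path(outdir, "tables",
                                                 "mirna_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$gene_mirna_sites,
                     file.path(outdir, "tables", "gene_mirna_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$gene_terms,
                     file.path(outdir, "tables", "gene_terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tw <- function(x, f) utils::write.table(
    x, file.path(outdir, "truth", f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tw(truth$circs, "circs.tsv")
  tw(truth$genes, "genes.tsv")
  tw(truth$expr_truth, "expression.tsv")
  tw(truth$planted_sites, "planted_sites.tsv")
  tw(truth$snp_records, "snp_records.tsv")
  pres <- as.data.frame(truth$presence)
  pres <- cbind(cell_id = rownames(pres), pres)
  utils::write.table(pres, file.path(outdir, "truth", "presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- list(
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
    gene_term_table = file.path(outdir, "tables", "gene_terms.tsv"))
  invisible(list(paths = paths, truth = truth, cfg = cfg))
}
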