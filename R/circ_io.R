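# Readers/writers for detector call tables, VCF, expression tables, GTF,
# chromosome sizes, FASTA and network files. Everything genomic is normalized
# to 0-based half-open coordinates and "chr"-prefixed chromosome names.

CIRC_TOOLS <- c("ciri", "circexplorer", "find_circ", "circrnafinder")

#' Normalize chromosome names
#'
#' Canonical names are "chr"-prefixed; un-prefixed names gain the prefix.
#'
#' @param x character vector of chromosome names.
#' @return character vector.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  bare <- !grepl("^chr", x)
  x[bare] <- paste0("chr", x[bare])
  x
}

circ_call_tibble <- function(cell_id, chrom, start, end, strand,
                             junction_reads, tool, host_gene = NA_character_) {
  tibble::tibble(
    cell_id = as.character(cell_id),
    chrom = normalize_chrom(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    junction_reads = as.integer(junction_reads),
    tool = as.character(tool),
    host_gene = as.character(host_gene)
  )
}

empty_circ_calls <- function() {
  circ_call_tibble(character(), character(), integer(), integer(),
                   character(), integer(), character(), character())
}

#' Validate a circRNA call table
#'
#' Checks the structural invariants of back-splice junction calls:
#' `start < end`, non-negative junction read counts, non-empty chromosome
#' names, strand in `+`, `-`, `.` and a known tool label.
#'
#' @param calls tibble as produced by [read_circ_calls()].
#' @return `calls`, invisibly; errors if an invariant is violated.
#' @export
validate_circ_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(is.na(calls$chrom) | !nzchar(calls$chrom)))
    stop("circ calls: empty chromosome name")
  if (any(calls$start >= calls$end))
    stop("circ calls: start must be < end")
  if (any(calls$junction_reads < 0))
    stop("circ calls: negative junction read count")
  if (!all(calls$strand %in% c("+", "-", ".")))
    stop("circ calls: strand must be one of +, -, .")
  if (!all(calls$tool %in% CIRC_TOOLS))
    stop("circ calls: unknown tool label")
  invisible(calls)
}

parse_fields <- function(path, n_min, skip_header_regex = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) > 0 && !is.null(skip_header_regex) &&
      grepl(skip_header_regex, lines[1])) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < n_min)
  if (length(short) > 0) {
    stop(sprintf("parse error in %s at line %d: expected >= %d tab-separated fields",
                 path, line_no[short[1]], n_min))
  }
  list(fields = fields, line_no = line_no)
}

as_num_or_fail <- function(x, path, line_no, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s at line %d: non-numeric %s field '%s'",
                 path, line_no[bad[1]], what, x[bad[1]]))
  }
  out
}

#' Read circRNA detector output in one of four dialects
#'
#' Supported dialects: `ciri` (CIRI2-style TSV, 1-based inclusive
#' coordinates), `find_circ` and `circrnafinder` (BED6, junction reads in the
#' score column), `circexplorer` (BED12-like annotated output, read number in
#' column 13 and gene name in column 15). All coordinates are converted to
#' the internal 0-based half-open convention: BED dialects pass through,
#' 1-based inclusive starts are decremented by one.
#'
#' @param path detector output file.
#' @param dialect one of `"ciri"`, `"find_circ"`, `"circexplorer"`,
#'   `"circrnafinder"`.
#' @param cell_id cell identifier attached to every call.
#' @return tibble of calls with columns `cell_id`, `chrom`, `start`, `end`,
#'   `strand`, `junction_reads`, `tool`, `host_gene`.
#' @export
read_circ_calls <- function(path, dialect, cell_id) {
  if (!dialect %in% CIRC_TOOLS)
    stop(sprintf("unknown dialect '%s'; supported: %s", dialect,
                 paste(CIRC_TOOLS, collapse = ", ")))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))

  if (dialect == "ciri") {
    p <- parse_fields(path, 11, skip_header_regex = "^circRNA_ID\t")
    if (length(p$fields) == 0) return(empty_circ_calls())
    f <- function(i) vapply(p$fields, `[[`, character(1), i)
    calls <- circ_call_tibble(
      cell_id = cell_id,
      chrom = f(2),
      start = as_num_or_fail(f(3), path, p$line_no, "start") - 1L,
      end = as_num_or_fail(f(4), path, p$line_no, "end"),
      strand = f(11),
      junction_reads = as_num_or_fail(f(5), path, p$line_no, "junction_reads"),
      tool = dialect,
      host_gene = ifelse(f(10) %in% c(".", "n/a", ""), NA_character_, f(10))
    )
  } else if (dialect == "circexplorer") {
    p <- parse_fields(path, 15)
    if (length(p$fields) == 0) return(empty_circ_calls())
    f <- function(i) vapply(p$fields, `[[`, character(1), i)
    calls <- circ_call_tibble(
      cell_id = cell_id,
      chrom = f(1),
      start = as_num_or_fail(f(2), path, p$line_no, "start"),
      end = as_num_or_fail(f(3), path, p$line_no, "end"),
      strand = f(6),
      junction_reads = as_num_or_fail(f(13), path, p$line_no, "readNumber"),
      tool = dialect,
      host_gene = ifelse(f(15) %in% c(".", "n/a", ""), NA_character_, f(15))
    )
  } else {
    p <- parse_fields(path, 6)
    if (length(p$fields) == 0) return(empty_circ_calls())
    f <- function(i) vapply(p$fields, `[[`, character(1), i)
    calls <- circ_call_tibble(
      cell_id = cell_id,
      chrom = f(1),
      start = as_num_or_fail(f(2), path, p$line_no, "start"),
      end = as_num_or_fail(f(3), path, p$line_no, "end"),
      strand = f(6),
      junction_reads = as_num_or_fail(f(5), path, p$line_no, "score"),
      tool = dialect
    )
  }
  validate_circ_calls(calls)
  calls
}

#' Write circRNA calls in a detector dialect
#'
#' Inverse of [read_circ_calls()]: converts internal 0-based half-open
#' coordinates back to the dialect's convention so a write/read round trip
#' is the identity.
#'
#' @param calls tibble of calls (internal convention).
#' @param path output file.
#' @param dialect output dialect (see [read_circ_calls()]).
#' @return `path`, invisibly.
#' @export
write_circ_calls <- function(calls, path, dialect) {
  if (!dialect %in% CIRC_TOOLS) stop(sprintf("unknown dialect '%s'", dialect))
  validate_circ_calls(calls)
  n <- nrow(calls)
  gene <- ifelse(is.na(calls$host_gene), ".", calls$host_gene)
  if (dialect == "ciri") {
    header <- paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                    "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
                    "junction_reads_ratio", "circRNA_type", "gene_id",
                    "strand", sep = "\t")
    rows <- if (n == 0) character() else sprintf(
      "%s:%d|%d\t%s\t%d\t%d\t%d\t0_0_0\t0\t1.0\texon\t%s\t%s",
      calls$chrom, calls$start + 1L, calls$end, calls$chrom,
      calls$start + 1L, calls$end, calls$junction_reads, gene, calls$strand)
    writeLines(c(header, rows), path)
  } else if (dialect == "circexplorer") {
    rows <- if (n == 0) character() else sprintf(
      paste0("%s\t%d\t%d\tcircular_RNA/%d\t0\t%s\t%d\t%d\t0,0,0\t1\t%d\t0\t",
             "%d\tcircRNA\t%s\tNA\t1\tNA"),
      calls$chrom, calls$start, calls$end, seq_len(n), calls$strand,
      calls$start, calls$end, calls$end - calls$start,
      calls$junction_reads, gene)
    writeLines(rows, path)
  } else {
    rows <- if (n == 0) character() else sprintf(
      "%s\t%d\t%d\t%s_circ_%d\t%d\t%s",
      calls$chrom, calls$start, calls$end, dialect, seq_len(n),
      calls$junction_reads, calls$strand)
    writeLines(rows, path)
  }
  invisible(path)
}

#' Read per-cell SNP calls from a VCF
#'
#' Parses a VCF 4.x file through `VariantAnnotation`, keeps biallelic SNVs
#' only, and extracts the QUAL, QD, DP and FS annotations used by the
#' hard-filtering step. Indels and multi-allelic rows are skipped; the number
#' skipped is reported in a message and attached as attribute `n_skipped`.
#' Positions are converted to the internal 0-based convention.
#'
#' @param path VCF file.
#' @param caller caller label, `"gatk"` or `"samtools"`.
#' @param cell_id cell identifier.
#' @return tibble with columns `cell_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qd`, `dp`, `fs`, `caller`.
#' @export
read_vcf <- function(path, caller, cell_id) {
  caller <- match.arg(caller, c("gatk", "samtools"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  is_biallelic <- S4Vectors::elementNROWS(altL) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[is_biallelic] <- as.character(unlist(altL[is_biallelic]))
  is_snv <- is_biallelic & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d non-SNP record(s) in %s",
                    n_skipped, basename(path)))
  info <- VariantAnnotation::info(vcf)
  get_info <- function(name) {
    if (name %in% colnames(info)) as.numeric(info[[name]]) else
      rep(NA_real_, length(ref))
  }
  out <- tibble::tibble(
    cell_id = as.character(cell_id),
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr))),
    pos = as.integer(GenomicRanges::start(rr) - 1L),
    ref = ref,
    alt = alt,
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    qd = get_info("QD"),
    dp = get_info("DP"),
    fs = get_info("FS"),
    caller = caller
  )[is_snv, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a per-cell gene expression table
#'
#' Expects a TSV with a header and columns `gene_id`, `read_count`, `fpkm`
#' (an optional `cell_id` column overrides the argument).
#'
#' @param path expression TSV.
#' @param cell_id cell identifier to attach when absent from the file.
#' @return tibble with `cell_id`, `gene_id`, `read_count`, `fpkm`.
#' @export
read_expression <- function(path, cell_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "read_count", "fpkm")
  if (!all(need %in% names(df)))
    stop(sprintf("expression table %s must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (!"cell_id" %in% names(df)) {
    if (is.null(cell_id)) stop("cell_id must be given when absent from file")
    df$cell_id <- cell_id
  }
  if (any(df$read_count < 0) || any(df$fpkm < 0))
    stop(sprintf("expression table %s: negative counts or FPKM", path))
  tibble::as_tibble(df[, c("cell_id", "gene_id", "read_count", "fpkm")])
}

#' Read chromosome lengths
#'
#' Two-column TSV (chromosome, length in bp), no header.
#'
#' @param path chrom-sizes file.
#' @return tibble with `chrom`, `length`.
#' @export
read_chrom_info <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  tibble::tibble(chrom = normalize_chrom(df$chrom),
                 length = as.integer(df$length))
}

#' Build a gene interval index from a GTF
#'
#' Imports gene annotation and returns a `GRanges` of gene spans (one range
#' per `gene_id`) for host-gene assignment by interval query.
#'
#' @param path GTF file.
#' @return `GRanges` with metadata column `gene_id`.
#' @export
read_gtf_gene_index <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  } else {
    # no explicit gene rows: collapse per gene_id
    spl <- split(gr, gr$gene_id)
    rng <- unlist(range(spl))
    rng$gene_id <- names(rng)
    gr <- rng
  }
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  gr
}

#' Assign back-splice junctions to host genes
#'
#' A junction is assigned to the gene whose span contains both endpoints.
#' When several genes qualify the tie is broken by (1) matching strand,
#' (2) longest overlap, (3) lexicographically smallest gene id. Junctions
#' contained in no gene keep `host_gene = NA`.
#'
#' @param calls circRNA call or consensus tibble with `chrom`, `start`,
#'   `end`, `strand` columns.
#' @param gene_index `GRanges` from [read_gtf_gene_index()].
#' @param overwrite replace existing `host_gene` values (default fills NA
#'   only).
#' @return `calls` with the `host_gene` column filled in.
#' @export
assign_host_genes <- function(calls, gene_index, overwrite = TRUE) {
  if (!"host_gene" %in% names(calls)) calls$host_gene <- NA_character_
  if (nrow(calls) == 0) return(calls)
  q <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = "*"
  )
  hits <- GenomicRanges::findOverlaps(q, gene_index, type = "within",
                                      ignore.strand = TRUE)
  assigned <- rep(NA_character_, nrow(calls))
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(q)[qh], IRanges::ranges(gene_index)[sh]))
    gene_strand <- as.character(GenomicRanges::strand(gene_index))[sh]
    gid <- as.character(gene_index$gene_id)[sh]
    same_strand <- gene_strand == calls$strand[qh]
    ord <- order(qh, !same_strand, -ov, gid)
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- gid[ord][first]
  }
  fill <- if (overwrite) rep(TRUE, nrow(calls)) else is.na(calls$host_gene)
  calls$host_gene[fill] <- assigned[fill]
  calls
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` normalizes U to T; `"RNA"` normalizes T to U.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (alphabet == "DNA") chartr("U", "T", seqs) else chartr("T", "U", seqs)
}

#' Read mature miRNA sequences
#'
#' Reads a miRNA FASTA (RNA alphabet) and extracts the seed region
#' (positions 2-8 of the mature sequence).
#'
#' @param path FASTA of mature miRNA sequences.
#' @return tibble with `mirna_id`, `sequence` (RNA), `seed` (positions 2-8).
#' @export
read_mirnas <- function(path) {
  seqs <- read_fasta(path, alphabet = "RNA")
  if (any(nchar(seqs) < 8)) stop("miRNA sequences must be at least 8 nt")
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) stop(sprintf("miRNA %s contains non-ACGU characters",
                             names(seqs)[bad][1]))
  tibble::tibble(
    mirna_id = names(seqs),
    sequence = unname(seqs),
    seed = substr(unname(seqs), 2, 8)
  )
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Export a network to SIF or GraphML
#'
#' SIF lines are `source<TAB>interaction<TAB>target` using the `type` edge
#' attribute as the interaction label (Cytoscape-loadable); GraphML goes
#' through `igraph::write_graph` and keeps all attributes.
#'
#' @param graph an `igraph` object with a `type` edge attribute.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    etype <- igraph::edge_attr(graph, "type")
    if (is.null(etype)) etype <- rep("interacts", nrow(el))
    writeLines(sprintf("%s\t%s\t%s", el[, 1], etype, el[, 2]), path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path network file.
#' @param format `"sif"` or `"graphml"`.
#' @return an `igraph` object.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad) > 0)
    stop(sprintf("parse error in %s at line %d: SIF rows need 3 fields",
                 path, bad[1]))
  el <- do.call(rbind, parts)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 3], type = el[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE)
  g
}
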