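# Consensus circRNA calling across detectors and SNP caller-consensus +
# hard filtering.

TOOL_PRIORITY <- c("ciri", "circexplorer", "find_circ", "circrnafinder")

circ_id_of <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)
}

#' Intersect circRNA calls across detection tools
#'
#' Per cell, a back-splice junction is kept iff a matching junction (same
#' chromosome and strand; coordinates equal in `exact` mode, or with both
#' endpoints within `window_bp` in `window` mode) was reported by every
#' required tool. Consensus coordinates are taken from the highest-priority
#' supporting tool (ciri > circexplorer > find_circ > circrnafinder) and the
#' consensus junction read count summarizes the supporting tools' counts.
#'
#' @param calls tibble of calls from [read_circ_calls()] (any mix of tools
#'   and cells).
#' @param required_tools tools that must all support a junction.
#' @param match_mode `"exact"` (default) or `"window"`.
#' @param window_bp tolerance per endpoint in window mode.
#' @param reads_summary `"max"` (default) or `"mean"` across supporting
#'   tools.
#' @param tools_provided tools actually run upstream; defaults to the tools
#'   present in `calls`. A required tool absent from this set is a
#'   configuration error (distinct from a tool that ran but found nothing).
#' @return tibble of consensus circRNAs: `circ_id`, `cell_id`, `chrom`,
#'   `start`, `end`, `strand`, `junction_reads`, `supporting_tools`,
#'   `host_gene`.
#' @export
intersect_calls <- function(calls, required_tools = TOOL_PRIORITY,
                            match_mode = c("exact", "window"),
                            window_bp = 2L,
                            reads_summary = c("max", "mean"),
                            tools_provided = NULL) {
  match_mode <- match.arg(match_mode)
  reads_summary <- match.arg(reads_summary)
  required_tools <- unique(required_tools)
  if (length(required_tools) == 0) stop("required_tools must be non-empty")
  if (!all(required_tools %in% TOOL_PRIORITY))
    stop("unknown tool in required_tools")
  if (is.null(tools_provided)) tools_provided <- unique(calls$tool)
  missing_tools <- setdiff(required_tools, tools_provided)
  if (length(missing_tools) > 0)
    stop(sprintf("required tool(s) not provided in input: %s",
                 paste(missing_tools, collapse = ", ")))
  validate_circ_calls(calls)

  empty <- tibble::tibble(
    circ_id = character(), cell_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    junction_reads = numeric(), supporting_tools = character(),
    host_gene = character())
  if (nrow(calls) == 0) return(empty)

  prio <- TOOL_PRIORITY[TOOL_PRIORITY %in% required_tools]
  out <- list()
  for (cell in unique(calls$cell_id)) {
    cc <- calls[calls$cell_id == cell, , drop = FALSE]
    if (match_mode == "exact") {
      key <- paste(cc$chrom, cc$start, cc$end, cc$strand)
      keys_by_tool <- lapply(required_tools, function(t) unique(key[cc$tool == t]))
      common <- Reduce(intersect, keys_by_tool)
      if (length(common) == 0) next
      sup <- cc[key %in% common, , drop = FALSE]
      sup$key <- paste(sup$chrom, sup$start, sup$end, sup$strand)
      sup$prio <- match(sup$tool, TOOL_PRIORITY)
      res <- lapply(split(sup, sup$key), function(g) {
        g <- g[order(g$prio), , drop = FALSE]
        reads <- if (reads_summary == "max") max(g$junction_reads)
                 else mean(g$junction_reads)
        hg <- g$host_gene[!is.na(g$host_gene)]
        tibble::tibble(
          circ_id = circ_id_of(g$chrom[1], g$start[1], g$end[1], g$strand[1]),
          cell_id = cell, chrom = g$chrom[1], start = g$start[1],
          end = g$end[1], strand = g$strand[1], junction_reads = reads,
          supporting_tools = paste(sort(unique(g$tool)), collapse = ","),
          host_gene = if (length(hg) > 0) hg[1] else NA_character_)
      })
      out[[length(out) + 1L]] <- dplyr::bind_rows(res)
    } else {
      anchor_tool <- prio[1]
      anchors <- cc[cc$tool == anchor_tool, , drop = FALSE]
      if (nrow(anchors) == 0) next
      others <- setdiff(required_tools, anchor_tool)
      res <- list()
      for (i in seq_len(nrow(anchors))) {
        a <- anchors[i, ]
        sup_reads <- a$junction_reads
        sup_tools <- anchor_tool
        hg <- a$host_gene
        ok <- TRUE
        for (t in others) {
          tc <- cc[cc$tool == t & cc$chrom == a$chrom & cc$strand == a$strand, ,
                   drop = FALSE]
          m <- tc[abs(tc$start - a$start) <= window_bp &
                  abs(tc$end - a$end) <= window_bp, , drop = FALSE]
          if (nrow(m) == 0) { ok <- FALSE; break }
          m <- m[order(abs(m$start - a$start) + abs(m$end - a$end)), ,
                 drop = FALSE]
          sup_reads <- c(sup_reads, m$junction_reads[1])
          sup_tools <- c(sup_tools, t)
          if (is.na(hg)) hg <- m$host_gene[1]
        }
        if (!ok) next
        reads <- if (reads_summary == "max") max(sup_reads) else mean(sup_reads)
        res[[length(res) + 1L]] <- tibble::tibble(
          circ_id = circ_id_of(a$chrom, a$start, a$end, a$strand),
          cell_id = cell, chrom = a$chrom, start = a$start, end = a$end,
          strand = a$strand, junction_reads = reads,
          supporting_tools = paste(sort(sup_tools), collapse = ","),
          host_gene = hg)
      }
      if (length(res) > 0) {
        block <- dplyr::bind_rows(res)
        block <- block[!duplicated(block$circ_id), , drop = FALSE]
        out[[length(out) + 1L]] <- block
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  res[order(res$cell_id, res$chrom, res$start, res$end), , drop = FALSE]
}

#' Hard-filter thresholds for SNP records
#'
#' Removal rules are strict inequalities on the removal side, so values
#' equal to a threshold are kept: records are dropped when QUAL < 30,
#' QD < 20.0, DP < 8 or FS > 30.0.
#'
#' @param qual_min minimum QUAL kept.
#' @param qd_min minimum QD kept.
#' @param dp_min minimum DP kept.
#' @param fs_max maximum FS kept.
#' @return named list of thresholds.
#' @export
snp_filter_thresholds <- function(qual_min = 30, qd_min = 20.0, dp_min = 8,
                                  fs_max = 30.0) {
  list(qual_min = qual_min, qd_min = qd_min, dp_min = dp_min, fs_max = fs_max)
}

#' Caller-consensus SNP filtering
#'
#' Keeps positions called by both GATK and Samtools (same cell, chromosome,
#' position, ref and alt allele), then applies the hard filters of
#' [snp_filter_thresholds()]. QUAL, QD, DP and FS annotations are taken from
#' the GATK record when callers disagree.
#'
#' @param records tibble of SNP records from [read_vcf()] covering both
#'   callers.
#' @param thresholds list from [snp_filter_thresholds()].
#' @return tibble of filtered SNPs: `cell_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qd`, `dp`, `fs`, `callers`.
#' @export
snp_consensus_filter <- function(records,
                                 thresholds = snp_filter_thresholds()) {
  stopifnot(is.data.frame(records))
  need <- c("cell_id", "chrom", "pos", "ref", "alt", "qual", "qd", "dp",
            "fs", "caller")
  if (!all(need %in% names(records)))
    stop("records must have the SnpRecord columns")
  g <- records[records$caller == "gatk", , drop = FALSE]
  s <- records[records$caller == "samtools", , drop = FALSE]
  key <- function(df) paste(df$cell_id, df$chrom, df$pos, df$ref, df$alt)
  g <- g[!duplicated(key(g)), , drop = FALSE]
  both <- g[key(g) %in% key(s), , drop = FALSE]
  keep <- !is.na(both$qual) & both$qual >= thresholds$qual_min &
    !is.na(both$qd) & both$qd >= thresholds$qd_min &
    !is.na(both$dp) & both$dp >= thresholds$dp_min &
    !is.na(both$fs) & both$fs <= thresholds$fs_max
  out <- both[keep, c("cell_id", "chrom", "pos", "ref", "alt", "qual", "qd",
                      "dp", "fs"), drop = FALSE]
  out$callers <- "gatk,samtools"
  tibble::as_tibble(out[order(out$cell_id, out$chrom, out$pos), ,
                        drop = FALSE])
}
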