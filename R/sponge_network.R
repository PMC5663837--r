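# miRNA seed-match scanning on circRNA sequences (including sites spanning
# the back-splice junction) and circRNA-miRNA-mRNA sponge-network assembly.

SEED_CLASSES <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
# target-side footprint in nt (seed-complementary region plus the A1
# position where the class requires it)
SEED_FOOTPRINT <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

empty_seed_matches <- function() {
  tibble::tibble(circ_id = character(), mirna_id = character(),
                 site_start = integer(), match_class = character())
}

# All (overlapping) start positions of fixed pattern `pat` in each sequence
# of `subject` (DNAStringSet); positions with N never match.
all_match_starts <- function(pat, subject) {
  m <- Biostrings::vmatchPattern(pat, subject, fixed = TRUE)
  lapply(seq_along(subject), function(i) BiocGenerics::start(m[[i]]))
}

scan_one_class_set <- function(seqs, mirnas) {
  # Returns, per miRNA, lists of 7mer-m8-region starts and 6mer-only starts
  # (1-based) for every sequence in `seqs` (named character, DNA).
  subject <- Biostrings::DNAStringSet(seqs)
  lapply(seq_len(nrow(mirnas)), function(k) {
    mseq <- chartr("U", "T", toupper(mirnas$sequence[k]))
    rc7 <- revcomp_dna(substr(mseq, 2, 8))
    rc6 <- revcomp_dna(substr(mseq, 2, 7))
    s7 <- all_match_starts(rc7, subject)
    s6 <- all_match_starts(rc6, subject)
    # a 7mer-m8 match at s implies a 6mer match at s+1; report it once
    s6only <- lapply(seq_along(s6), function(i) setdiff(s6[[i]], s7[[i]] + 1L))
    list(s7 = s7, s6only = s6only)
  })
}

classify_sites <- function(seqs, scans, mirnas) {
  ids <- names(seqs)
  out <- list()
  for (k in seq_along(scans)) {
    sc <- scans[[k]]
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      if (length(sc$s7[[i]]) > 0) {
        a_next <- substr(rep(s, length(sc$s7[[i]])), sc$s7[[i]] + 7L,
                         sc$s7[[i]] + 7L) == "A"
        out[[length(out) + 1L]] <- tibble::tibble(
          circ_id = ids[i], mirna_id = mirnas$mirna_id[k],
          site_start = as.integer(sc$s7[[i]] - 1L),
          match_class = ifelse(a_next, "8mer", "7mer-m8"))
      }
      if (length(sc$s6only[[i]]) > 0) {
        a_next <- substr(rep(s, length(sc$s6only[[i]])), sc$s6only[[i]] + 6L,
                         sc$s6only[[i]] + 6L) == "A"
        out[[length(out) + 1L]] <- tibble::tibble(
          circ_id = ids[i], mirna_id = mirnas$mirna_id[k],
          site_start = as.integer(sc$s6only[[i]] - 1L),
          match_class = ifelse(a_next, "7mer-A1", "6mer"))
      }
    }
  }
  if (length(out) == 0) return(empty_seed_matches())
  dplyr::bind_rows(out)
}

#' Scan circRNA sequences for miRNA seed-match sites
#'
#' Finds every target site whose sequence is the reverse complement (DNA
#' alphabet) of the miRNA seed region, graded by canonical classes: 6mer
#' (miRNA positions 2-7), 7mer-m8 (2-8), 7mer-A1 (2-7 plus an A opposite
#' miRNA position 1) and 8mer (2-8 plus A1). Overlapping sites are all
#' reported; each site carries its best class. The scan is linear (sense
#' orientation only); see [circ_junction_site_scan()] for sites spanning
#' the back-splice junction. `N` positions never match.
#'
#' @param circ_seqs named character vector of circRNA sequences (DNA; U is
#'   normalized to T) or a single unnamed sequence.
#' @param mirnas tibble from [read_mirnas()] (columns `mirna_id`,
#'   `sequence`).
#' @param min_class minimum reported stringency, one of `"6mer"`,
#'   `"7mer-A1"`, `"7mer-m8"` (default), `"8mer"`.
#' @return tibble with `circ_id`, `mirna_id`, `site_start` (0-based offset
#'   of the seed-complementary region), `match_class`.
#' @export
scan_seed_sites <- function(circ_seqs, mirnas, min_class = "7mer-m8") {
  min_class <- match.arg(min_class, names(SEED_CLASSES))
  circ_seqs <- prep_circ_seqs(circ_seqs)
  if (length(circ_seqs) == 0 || all(nchar(circ_seqs) == 0))
    return(empty_seed_matches())
  scans <- scan_one_class_set(circ_seqs, mirnas)
  res <- classify_sites(circ_seqs, scans, mirnas)
  res <- res[SEED_CLASSES[res$match_class] >= SEED_CLASSES[min_class], ,
             drop = FALSE]
  res[order(res$circ_id, res$mirna_id, res$site_start), , drop = FALSE]
}

prep_circ_seqs <- function(circ_seqs) {
  if (length(circ_seqs) == 1 && is.null(names(circ_seqs)))
    names(circ_seqs) <- "circ_1"
  if (is.null(names(circ_seqs)) || any(!nzchar(names(circ_seqs))))
    stop("circ_seqs must be named")
  toupper(chartr("U", "T", circ_seqs))
}

#' Seed-match sites spanning the back-splice junction
#'
#' circRNAs are covalently closed, so a target site can wrap from the end of
#' the (linearized) sequence into its start. The scan runs on the sequence
#' extended by its first 7 nt and keeps only sites whose footprint crosses
#' the end-to-start junction; `site_start` stays in modular (0-based)
#' coordinates of the original sequence.
#'
#' @inheritParams scan_seed_sites
#' @return tibble as in [scan_seed_sites()], junction-crossing sites only.
#' @export
circ_junction_site_scan <- function(circ_seqs, mirnas,
                                    min_class = "7mer-m8") {
  min_class <- match.arg(min_class, names(SEED_CLASSES))
  circ_seqs <- prep_circ_seqs(circ_seqs)
  if (length(circ_seqs) == 0) return(empty_seed_matches())
  L <- nchar(circ_seqs)
  ext <- paste0(circ_seqs, substr(circ_seqs, 1, 7))
  names(ext) <- names(circ_seqs)
  scans <- scan_one_class_set(ext, mirnas)
  res <- classify_sites(ext, scans, mirnas)
  if (nrow(res) == 0) return(res)
  res <- res[SEED_CLASSES[res$match_class] >= SEED_CLASSES[min_class], ,
             drop = FALSE]
  Lv <- L[res$circ_id]
  fp <- SEED_FOOTPRINT[res$match_class]
  keep <- res$site_start < Lv & res$site_start + fp > Lv
  res <- res[keep, , drop = FALSE]
  res[order(res$circ_id, res$mirna_id, res$site_start), , drop = FALSE]
}

#' Full circular scan
#'
#' Union of the linear scan and the junction-spanning scan.
#'
#' @inheritParams scan_seed_sites
#' @return tibble as in [scan_seed_sites()].
#' @export
scan_seed_sites_circular <- function(circ_seqs, mirnas,
                                     min_class = "7mer-m8") {
  res <- dplyr::bind_rows(
    scan_seed_sites(circ_seqs, mirnas, min_class),
    circ_junction_site_scan(circ_seqs, mirnas, min_class))
  res[order(res$circ_id, res$mirna_id, res$site_start), , drop = FALSE]
}

#' Assemble a circRNA-miRNA-mRNA sponge network
#'
#' Builds a tripartite graph with typed nodes (circRNA, miRNA, gene) and
#' typed edges: circ-mir edges from seed matches (multiplicity = number of
#' sites) and mir-gene edges from a user-supplied association table
#' (multiplicity = duplicated table rows). miRNAs with no gene association
#' remain in the circ-mir layer. `restrict_genes` drops gene nodes outside
#' the set (an empty set empties the gene layer without touching the
#' circ-mir layer); nodes left without any edge are removed.
#'
#' @param seed_matches tibble from [scan_seed_sites()].
#' @param mirna_gene_table tibble with `mirna_id`, `gene_id`.
#' @param restrict_genes optional character vector of gene ids to keep
#'   (`NULL` keeps all).
#' @return an `igraph` object with vertex attribute `type` in
#'   \{`circRNA`, `miRNA`, `gene`\} and edge attributes `type`
#'   (`seed_match` / `association`) and `multiplicity`.
#' @export
build_sponge_network <- function(seed_matches, mirna_gene_table,
                                 restrict_genes = NULL) {
  cm <- dplyr::count(seed_matches, circ_id, mirna_id, name = "multiplicity")
  mg <- mirna_gene_table[mirna_gene_table$mirna_id %in% cm$mirna_id, ,
                         drop = FALSE]
  if (!is.null(restrict_genes))
    mg <- mg[mg$gene_id %in% restrict_genes, , drop = FALSE]
  mg <- dplyr::count(tibble::as_tibble(mg), mirna_id, gene_id,
                     name = "multiplicity")
  edges <- rbind(
    data.frame(from = cm$circ_id, to = cm$mirna_id,
               type = rep("seed_match", nrow(cm)),
               multiplicity = cm$multiplicity, stringsAsFactors = FALSE),
    data.frame(from = mg$mirna_id, to = mg$gene_id,
               type = rep("association", nrow(mg)),
               multiplicity = mg$multiplicity, stringsAsFactors = FALSE))
  vert_block <- function(ids, type)
    data.frame(name = ids, type = rep(type, length(ids)),
               stringsAsFactors = FALSE)
  verts <- rbind(vert_block(unique(cm$circ_id), "circRNA"),
                 vert_block(unique(cm$mirna_id), "miRNA"),
                 vert_block(unique(mg$gene_id), "gene"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g
}

#' Top sponge-regulator miRNAs
#'
#' Ranks miRNAs by the number of distinct circRNAs they match; ties are
#' broken by miRNA id.
#'
#' @param seed_matches tibble from [scan_seed_sites()].
#' @param k number of miRNAs to return (the full ranking when larger than
#'   the number of matched miRNAs).
#' @return tibble with `mirna_id`, `n_circ` (distinct circRNAs matched),
#'   in rank order.
#' @export
top_regulator_mirnas <- function(seed_matches, k = 10) {
  if (nrow(seed_matches) == 0)
    return(tibble::tibble(mirna_id = character(), n_circ = integer()))
  deg <- dplyr::distinct(seed_matches, mirna_id, circ_id)
  deg <- dplyr::count(deg, mirna_id, name = "n_circ")
  deg <- deg[order(-deg$n_circ, deg$mirna_id), , drop = FALSE]
  utils::head(deg, k)
}

#' Re-verify reported seed matches
#'
#' Self-check: every reported site must re-verify by direct
#' reverse-complement comparison of the class-defining miRNA positions with
#' the circRNA subsequence (wrapping around the junction if needed).
#'
#' @param matches tibble from [scan_seed_sites()] or
#'   [circ_junction_site_scan()].
#' @param circ_seqs named character vector of circRNA sequences.
#' @param mirnas tibble from [read_mirnas()].
#' @return logical vector, one entry per match.
#' @export
verify_seed_matches <- function(matches, circ_seqs, mirnas) {
  circ_seqs <- prep_circ_seqs(circ_seqs)
  mseq <- stats::setNames(chartr("U", "T", toupper(mirnas$sequence)),
                          mirnas$mirna_id)
  vapply(seq_len(nrow(matches)), function(i) {
    s <- circ_seqs[[matches$circ_id[i]]]
    L <- nchar(s)
    cls <- matches$match_class[i]
    m <- mseq[[matches$mirna_id[i]]]
    core <- if (cls %in% c("6mer", "7mer-A1")) substr(m, 2, 7) else
      substr(m, 2, 8)
    expect <- revcomp_dna(core)
    if (cls %in% c("7mer-A1", "8mer")) expect <- paste0(expect, "A")
    idx <- (matches$site_start[i] + seq_len(nchar(expect)) - 1L) %% L + 1L
    got <- paste(substring(s, idx, idx), collapse = "")
    identical(got, expect)
  }, logical(1))
}
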