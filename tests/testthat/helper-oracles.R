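# Independent brute-force oracles, written as plain loops and kept separate
# from the package implementations they check.

# pairwise Manhattan distance by explicit double loop
oracle_manhattan <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (f in seq_len(ncol(m))) s <- s + abs(m[i, f] - m[j, f])
      d[i, j] <- s
    }
  }
  d
}

# running-sum enrichment score by explicit accumulation
oracle_es <- function(genes, metric, query, weight_p) {
  ord <- order(-metric, genes)
  g <- genes[ord]
  m <- metric[ord]
  hit <- g %in% query
  N <- length(g)
  Nh <- sum(hit)
  sumw <- if (weight_p == 0) Nh else sum(abs(m[hit]))
  cur <- 0
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + (if (weight_p == 0) 1 else abs(m[i])) / sumw
    } else {
      cur <- cur - 1 / (N - Nh)
    }
    if (cur > mx) mx <- cur
    if (cur < mn) mn <- cur
  }
  # same tie rule as the implementation: equal magnitudes -> positive
  if (abs(mx + mn) < 1e-9 || mx + mn > 0) mx else mn
}

naive_rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# naive all-offset substring comparison, one sequence x one miRNA
oracle_seed_scan <- function(circ_seq, mseq_rna) {
  mseq <- chartr("U", "T", mseq_rna)
  rc7 <- naive_rc(substr(mseq, 2, 8))
  rc6 <- naive_rc(substr(mseq, 2, 7))
  L <- nchar(circ_seq)
  out <- list()
  if (L >= 7) {
    for (s in 1:(L - 6)) {
      if (substr(circ_seq, s, s + 6) == rc7) {
        cls <- if (s + 7 <= L && substr(circ_seq, s + 7, s + 7) == "A")
          "8mer" else "7mer-m8"
        out[[length(out) + 1]] <- data.frame(site_start = s - 1,
                                             match_class = cls)
      }
    }
  }
  if (L >= 6) {
    for (s in 1:(L - 5)) {
      if (substr(circ_seq, s, s + 5) == rc6) {
        if (s >= 2 && substr(circ_seq, s - 1, s + 5) == rc7) next
        cls <- if (s + 6 <= L && substr(circ_seq, s + 6, s + 6) == "A")
          "7mer-A1" else "6mer"
        out[[length(out) + 1]] <- data.frame(site_start = s - 1,
                                             match_class = cls)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(site_start = integer(), match_class = character()))
  do.call(rbind, out)
}

# naive all-pairs consensus: a call survives iff every required tool has an
# exactly matching call in the same cell
oracle_consensus_keys <- function(calls, required_tools) {
  out <- character()
  for (cell in unique(calls$cell_id)) {
    cc <- calls[calls$cell_id == cell, ]
    keys <- unique(paste(cc$chrom, cc$start, cc$end, cc$strand))
    for (k in keys) {
      ok <- TRUE
      for (t in required_tools) {
        tc <- cc[cc$tool == t, ]
        if (!k %in% paste(tc$chrom, tc$start, tc$end, tc$strand)) {
          ok <- FALSE
          break
        }
      }
      if (ok) out <- c(out, paste(cell, k))
    }
  }
  sort(out)
}

random_dna_str <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

random_rna_str <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# small cohort configuration used across tests (kept small for speed; the
# statistical structure matches the package defaults)
small_sim_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cells = 6L, n_circ = 40L, n_genes = 120L, n_mirnas = 20L,
         n_planted_regulator = 8L, seed = seed),
    list(...))
  do.call(sim_config, args)
}
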