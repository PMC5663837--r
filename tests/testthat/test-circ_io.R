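# Readers/writers: dialect coordinate conventions, round trips, VCF SNP
# extraction, host-gene assignment, FASTA and network IO.

test_that("BED dialects pass coordinates through; CIRI converts 1-based", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tcirc_1\t5\t+", bed)
  calls <- read_circ_calls(bed, "find_circ", "cellA")
  expect_equal(calls$start, 100L)
  expect_equal(calls$end, 200L)
  expect_equal(calls$junction_reads, 5L)
  expect_equal(calls$cell_id, "cellA")

  ciri <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
          "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
          "junction_reads_ratio", "circRNA_type", "gene_id", "strand",
          sep = "\t"),
    "chr1:101|200\tchr1\t101\t200\t5\t0_0_0\t0\t1.0\texon\tGENE1\t+"), ciri)
  calls <- read_circ_calls(ciri, "ciri", "cellA")
  expect_equal(calls$start, 100L)
  expect_equal(calls$end, 200L)
  expect_equal(calls$junction_reads, 5L)
  expect_equal(calls$host_gene, "GENE1")
})

test_that("empty files give empty call tables; errors name the problem", {
  empty <- tempfile()
  writeLines(character(), empty)
  expect_equal(nrow(read_circ_calls(empty, "circrnafinder", "c")), 0)

  expect_error(read_circ_calls(empty, "not_a_tool", "c"), "unknown dialect")
  expect_error(read_circ_calls("/nonexistent/file", "ciri", "c"),
               "not found")

  bad <- tempfile()
  writeLines(c("chr1\t1\t10\tx\t2\t+", "chr1\tbroken"), bad)
  expect_error(read_circ_calls(bad, "find_circ", "c"), "line 2")
})

test_that("write/read round trip is the identity for every dialect", {
  withr::with_seed(11, {
    n <- 25
    chrom <- sample(paste0("chr", c(1:5, "X")), n, replace = TRUE)
    start <- sample.int(1e6, n)
    calls0 <- tibble::tibble(
      cell_id = "cell_1", chrom = chrom, start = as.integer(start),
      end = as.integer(start + sample(100:5000, n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      junction_reads = sample.int(50, n),
      tool = "ciri",
      host_gene = sample(c("G1", "G2", NA), n, replace = TRUE))
  })
  for (dialect in c("ciri", "circexplorer", "find_circ", "circrnafinder")) {
    calls <- calls0
    calls$tool <- dialect
    # BED6 dialects do not carry a gene column
    if (dialect %in% c("find_circ", "circrnafinder"))
      calls$host_gene <- NA_character_
    f <- tempfile()
    write_circ_calls(calls, f, dialect)
    back <- read_circ_calls(f, dialect, "cell_1")
    expect_equal(as.data.frame(back), as.data.frame(calls),
                 ignore_attr = TRUE)
  }
})

test_that("read_vcf extracts SNVs with annotations and skips indels", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\t.\tA\tG\t50\t.\tDP=10;QD=25;FS=1.0",
    "chr1\t2000\t.\tAT\tA\t60\t.\tDP=12;QD=30;FS=0.5",
    "chr2\t300\t.\tC\tT\t40\t.\tDP=9;QD=21;FS=2.0"), f)
  snps <- suppressMessages(read_vcf(f, "gatk", "cell_1"))
  expect_equal(nrow(snps), 2)
  expect_equal(attr(snps, "n_skipped"), 1)
  expect_equal(snps$pos, c(999L, 299L))   # 0-based internally
  expect_equal(snps$qual[1], 50)
  expect_equal(snps$qd[1], 25)
  expect_equal(snps$dp[1], 10)
  expect_equal(snps$fs[1], 1.0)
  expect_equal(snps$caller, rep("gatk", 2))
})

test_that("generator-written VCF round-trips through read_vcf", {
  fx <- fixture_minimal()
  f <- tempfile(fileext = ".vcf")
  rec <- fx$snp_records[fx$snp_records$caller == "gatk", ]
  circkit:::write_vcf_text(rec, f)
  back <- suppressMessages(read_vcf(f, "gatk", "cell_1"))
  expect_equal(nrow(back), nrow(rec))
  expect_setequal(back$pos, rec$pos)
  ord <- match(paste(rec$chrom, rec$pos), paste(back$chrom, back$pos))
  expect_equal(back$qual[ord], rec$qual)
  expect_equal(back$qd[ord], rec$qd)
  expect_equal(back$fs[ord], rec$fs)
  expect_equal(back$dp[ord], rec$dp)
})

test_that("host-gene assignment requires containment and prefers strand,
          then overlap, then id", {
  gi <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(1, 50, 40, 1), end = c(500, 400, 600, 100)),
    strand = c("+", "-", "+", "+"))
  gi$gene_id <- c("gplus", "gminus", "gwide", "gother")
  calls <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(100L, 100L, 200L, 450L),
    end = c(200L, 200L, 300L, 550L),
    strand = c("+", "-", "+", "+"),
    host_gene = NA_character_)
  out <- assign_host_genes(calls, gi)
  # two same-strand candidates (gplus, gwide) tie on containment overlap;
  # the lexicographically smaller id wins. Opposite strand loses first.
  expect_equal(out$host_gene[1], "gplus")
  expect_equal(out$host_gene[2], "gminus")
  # no containing gene -> NA, not an error
  expect_true(is.na(out$host_gene[3]))
  # contained only in gwide (past gplus's end)
  expect_equal(out$host_gene[4], "gwide")
})

test_that("FASTA and network exports round trip", {
  seqs <- c(a = "ACGTACGT", b = "GGGCCC")
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f, "DNA"), seqs)
  expect_equal(read_fasta(f, "RNA"), c(a = "ACGUACGU", b = "GGGCCC"))

  g <- igraph::graph_from_data_frame(
    data.frame(from = c("circ1", "m1"), to = c("m1", "gene1"),
               type = c("seed_match", "association")), directed = FALSE)
  for (fmt in c("sif", "graphml")) {
    nf <- tempfile()
    write_network(g, nf, fmt)
    back <- read_network(nf, fmt)
    expect_setequal(igraph::V(back)$name, c("circ1", "m1", "gene1"))
    edges_of <- function(gr) {
      el <- igraph::as_edgelist(gr)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_equal(edges_of(back), edges_of(g))
  }
})

test_that("chromosome names are normalized on read", {
  f <- tempfile()
  writeLines(c("1\t1000", "chr2\t500"), f)
  ci <- read_chrom_info(f)
  expect_equal(ci$chrom, c("chr1", "chr2"))
  expect_error({
    f2 <- tempfile()
    writeLines("chr1\t-5", f2)
    read_chrom_info(f2)
  }, "positive")
})
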