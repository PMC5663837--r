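# Consensus intersection semantics and SNP caller-consensus hard filtering.

make_call <- function(cell, tool, chrom = "chr1", start = 100L, end = 200L,
                      strand = "+", reads = 5L) {
  tibble::tibble(cell_id = cell, chrom = chrom, start = start, end = end,
                 strand = strand, junction_reads = reads, tool = tool,
                 host_gene = NA_character_)
}

all_tools <- c("ciri", "circexplorer", "find_circ", "circrnafinder")

test_that("a junction needs every required tool; 3 of 4 is dropped", {
  calls4 <- dplyr::bind_rows(lapply(all_tools, function(t)
    make_call("c1", t, reads = match(t, all_tools))))
  cons <- intersect_calls(calls4, all_tools)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$junction_reads, 4)  # max across tools
  expect_equal(cons$supporting_tools, paste(sort(all_tools), collapse = ","))

  calls3 <- calls4[calls4$tool != "ciri", ]
  expect_equal(nrow(intersect_calls(calls3, all_tools,
                                    tools_provided = all_tools)), 0)
  # mean summary option
  cons_mean <- intersect_calls(calls4, all_tools, reads_summary = "mean")
  expect_equal(cons_mean$junction_reads, mean(1:4))
})

test_that("a required tool absent from the input is a configuration error", {
  calls <- dplyr::bind_rows(lapply(all_tools[1:3], function(t)
    make_call("c1", t)))
  expect_error(intersect_calls(calls, all_tools), "circrnafinder")
})

test_that("window mode matches within the tolerance and keeps priority-tool
          coordinates", {
  calls <- dplyr::bind_rows(
    make_call("c1", "ciri", start = 100L, end = 200L),
    make_call("c1", "circexplorer", start = 101L, end = 199L),
    make_call("c1", "find_circ", start = 102L, end = 200L),
    make_call("c1", "circrnafinder", start = 99L, end = 201L))
  expect_equal(nrow(intersect_calls(calls, all_tools, "exact")), 0)
  cons <- intersect_calls(calls, all_tools, "window", window_bp = 2L)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100L)  # ciri is the priority anchor
  expect_equal(cons$end, 200L)
  # beyond the window the junction is lost
  expect_equal(nrow(intersect_calls(calls, all_tools, "window",
                                    window_bp = 1L)), 0)
})

test_that("intersection is monotone in the required tool set and matches a
          brute-force oracle", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      rows <- list()
      for (cell in c("c1", "c2")) {
        for (t in all_tools) {
          n <- sample(5:20, 1)
          st <- sample(seq(0, 1000, by = 10), n)
          rows[[length(rows) + 1]] <- tibble::tibble(
            cell_id = cell, chrom = sample(c("chr1", "chr2"), n, TRUE),
            start = as.integer(st), end = as.integer(st + 100L),
            strand = sample(c("+", "-"), n, TRUE),
            junction_reads = sample.int(10, n, TRUE), tool = t,
            host_gene = NA_character_)
        }
      }
      calls <- dplyr::bind_rows(rows)
      sizes <- integer()
      for (k in 2:4) {
        req <- all_tools[1:k]
        cons <- intersect_calls(calls, req, tools_provided = all_tools)
        got <- sort(paste(cons$cell_id, cons$chrom, cons$start, cons$end,
                          cons$strand))
        expect_equal(got, oracle_consensus_keys(
          calls[calls$tool %in% req, ], req))
        sizes <- c(sizes, nrow(cons))
      }
      expect_true(all(diff(sizes) <= 0))
    }
  })
})

test_that("SNP filter keeps caller-consensus records passing all hard
          filters, boundaries inclusive on the keep side", {
  fx <- fixture_minimal()
  out <- snp_consensus_filter(fx$snp_records)
  expect_equal(sort(out$pos), sort(fx$expected_snp_survivor_pos))
  # boundary record QUAL=30, QD=20, DP=8, FS=30 is among the survivors
  expect_true(500L %in% out$pos)
  # every survivor satisfies the FilteredSnp invariants
  expect_true(all(out$qual >= 30 & out$qd >= 20 & out$dp >= 8 &
                    out$fs <= 30))
  expect_true(all(out$callers == "gatk,samtools"))

  # DP = 7 with everything else passing is dropped
  rec <- dplyr::bind_rows(
    tibble::tibble(cell_id = "c", chrom = "chr1", pos = 1L, ref = "A",
                   alt = "G", qual = 99, qd = 30, dp = 7L, fs = 0,
                   caller = "gatk"),
    tibble::tibble(cell_id = "c", chrom = "chr1", pos = 1L, ref = "A",
                   alt = "G", qual = 99, qd = 30, dp = 7L, fs = 0,
                   caller = "samtools"))
  expect_equal(nrow(snp_consensus_filter(rec)), 0)
})

test_that("GATK annotations are authoritative when callers disagree", {
  rec <- dplyr::bind_rows(
    tibble::tibble(cell_id = "c", chrom = "chr1", pos = 1L, ref = "A",
                   alt = "G", qual = 50, qd = 25, dp = 20L, fs = 1,
                   caller = "gatk"),
    tibble::tibble(cell_id = "c", chrom = "chr1", pos = 1L, ref = "A",
                   alt = "G", qual = 10, qd = 2, dp = 3L, fs = 50,
                   caller = "samtools"))
  out <- snp_consensus_filter(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$qd, 25)
})
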