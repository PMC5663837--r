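# Running-sum enrichment score and permutation null.

test_that("all hits leading a 4-gene list walk to ES = 1", {
  rl <- ranked_gene_list(paste0("g", 1:4), c(4, 3, 2, 1), c("g1", "g2"))
  res <- enrichment_score(rl, weight_p = 0)
  expect_equal(res$running_sum, c(0.5, 1.0, 0.5, 0.0))
  expect_equal(res$es, 1.0)
  expect_equal(res$hit_positions, c(1L, 2L))
})

test_that("query in the bottom half mirrors to ES = -1", {
  rl <- ranked_gene_list(paste0("g", 1:10), 10:1, paste0("g", 6:10))
  res <- enrichment_score(rl, weight_p = 0)
  expect_equal(res$es, -1.0)
  expect_equal(res$running_sum[5], -1.0)
  expect_equal(res$running_sum[10], 0.0)
})

test_that("the running sum ends at 0 and stays within [-1, 1] for
          weight_p = 0", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      N <- sample(10:60, 1)
      genes <- paste0("g", sample.int(1e4, N))
      metric <- rnorm(N)
      q <- sample(genes, sample(2:(N - 1), 1))
      res <- enrichment_score(ranked_gene_list(genes, metric, q), 0)
      expect_equal(res$running_sum[N], 0, tolerance = 1e-12)
      expect_true(all(abs(res$running_sum) <= 1 + 1e-12))
    }
  })
})

test_that("ES is antisymmetric under list reversal for weight_p = 0", {
  withr::with_seed(32, {
    for (rep in 1:20) {
      N <- sample(10:50, 1)
      genes <- paste0("g", seq_len(N))
      metric <- sort(runif(N), decreasing = TRUE)  # strict, no ties
      q <- sample(genes, 5)
      es_fwd <- enrichment_score(ranked_gene_list(genes, metric, q), 0)$es
      es_rev <- enrichment_score(
        ranked_gene_list(genes, rev(metric), q), 0)$es
      expect_equal(es_fwd, -es_rev, tolerance = 1e-12)
    }
  })
})

test_that("degenerate query sets error", {
  rl <- ranked_gene_list(paste0("g", 1:4), 4:1, paste0("g", 1:4))
  expect_error(enrichment_score(rl), "full list")
  rl2 <- ranked_gene_list(paste0("g", 1:4), 4:1, "absent")
  expect_error(enrichment_score(rl2), "no gene")
})

test_that("ES agrees with the independently written walk and with fgsea", {
  has_fgsea <- requireNamespace("fgsea", quietly = TRUE)
  withr::with_seed(33, {
    for (rep in 1:50) {
      N <- sample(20:80, 1)
      genes <- paste0("g", sample.int(1e5, N))
      metric <- round(rexp(N), 3)
      q <- sample(genes, sample(3:10, 1))
      for (wp in c(0, 1)) {
        rl <- ranked_gene_list(genes, metric, q)
        expect_equal(enrichment_score(rl, wp)$es,
                     oracle_es(genes, metric, q, wp), tolerance = 1e-12)
      }
      if (has_fgsea) {
        # cross-check against fgsea's preranked statistic (gseaParam = 1
        # weights hits by |stat|, matching weight_p = 1); use a tie-free
        # metric so both rankings coincide
        metric2 <- sort(runif(N), decreasing = TRUE)
        rl2 <- ranked_gene_list(genes, metric2, q)
        stats_vec <- setNames(rl2$metric, rl2$gene)
        es_fgsea <- fgsea::calcGseaStat(
          stats_vec, selectedStats = which(rl2$gene %in% q), gseaParam = 1)
        expect_equal(enrichment_score(rl2, 1)$es, es_fgsea,
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("permutation p is reproducible given the seed and powered on an
          extreme configuration", {
  withr::with_seed(34, {
    genes <- paste0("g", 1:100)
    metric <- sort(rexp(100), decreasing = TRUE)
    rl <- ranked_gene_list(genes, metric, genes[1:10])  # top decile
    p1 <- permutation_p(rl, n_perm = 1000, weight_p = 0, seed = 99)
    p2 <- permutation_p(rl, n_perm = 1000, weight_p = 0, seed = 99)
    expect_equal(p1$perm_p, p2$perm_p)
    expect_lte(p1$perm_p, 0.01)
    expect_error(permutation_p(rl, n_perm = 50), ">= 100")
  })
})

test_that("tie handling is deterministic: equal metrics rank by gene id", {
  genes <- c("b", "a", "d", "c")
  rl <- ranked_gene_list(genes, c(1, 1, 1, 1), c("a", "b"))
  expect_equal(rl$gene, c("a", "b", "c", "d"))
  es1 <- enrichment_score(rl, 1)$es
  rl_shuffled <- ranked_gene_list(rev(genes), c(1, 1, 1, 1), c("a", "b"))
  expect_equal(enrichment_score(rl_shuffled, 1)$es, es1)
})

test_that("build_ranked_lists filters zeros and signs follow placement", {
  gene_fpkm <- tibble::tibble(gene_id = paste0("g", 1:10),
                              fpkm = c(10:2, 0))
  snps <- tibble::tibble(gene_id = paste0("g", 1:4), n_snps = c(3L, 2L,
                                                                1L, 1L))
  sites <- tibble::tibble(gene_id = paste0("g", 5:8), n_sites = 4:1)
  lists <- build_ranked_lists(gene_fpkm, snps, sites,
                              host_genes = paste0("g", 1:3))
  expect_equal(length(lists$expression$gene), 9)  # zero-FPKM gene dropped
  expect_equal(lists$expression$query_set, paste0("g", 1:3))
  # hosts lead the expression ranking -> positive ES
  expect_gt(enrichment_score(lists$expression, 0)$es, 0)
  expect_setequal(lists$snp$gene, paste0("g", 1:4))
  expect_setequal(lists$mirna$gene, paste0("g", 5:8))
})
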