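# CGR / circRNA-FPKM formulas, presence matrices, Manhattan distances,
# clustering and correlation.

test_that("CGR is the exact quotient, NA at zero host reads", {
  expect_equal(compute_cgr(5L, 50L), 0.1)
  expect_equal(compute_cgr(0L, 50L), 0)
  expect_true(is.na(compute_cgr(3L, 0L)))
  expect_error(compute_cgr(-1L, 10L), "non-negative")
  # vectorized and linear in junction reads
  expect_equal(compute_cgr(c(2L, 4L), c(10L, 10L)), c(0.2, 0.4))
})

test_that("circRNA FPKM normalizes by library size and host FPKM", {
  expect_equal(compute_circ_fpkm(10L, 2.0, 5.0), 1.0)
  expect_true(is.na(compute_circ_fpkm(10L, 1.0, 0.0)))
  expect_true(is.na(compute_circ_fpkm(10L, 0.0, 5.0)))
  expect_equal(compute_circ_fpkm(0L, 2.0, 5.0), 0)
  expect_error(compute_circ_fpkm(1L, -2, 5), "non-negative")
})

test_that("presence matrix equals the fixture's hand enumeration", {
  fx <- fixture_minimal()
  cons <- intersect_calls(fx$calls)
  pm <- presence_matrix(cons)
  expect_equal(pm[rownames(fx$expected_presence),
                  colnames(fx$expected_presence)],
               fx$expected_presence)
  # a cell with no circRNAs gives an all-zero row
  pm2 <- presence_matrix(cons, cells = c(rownames(pm), "cell_4"))
  expect_equal(sum(pm2["cell_4", ]), 0)
})

test_that("Manhattan distance equals brute-force discordance and satisfies
          metric axioms", {
  fx <- fixture_minimal()
  cons <- intersect_calls(fx$calls)
  pm <- presence_matrix(cons)
  md <- manhattan_distances(pm)
  expect_equal(md[rownames(fx$expected_manhattan),
                  colnames(fx$expected_manhattan)],
               fx$expected_manhattan)

  withr::with_seed(21, {
    for (rep in 1:10) {
      m <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8,
                  dimnames = list(paste0("c", 1:8), NULL))
      d <- manhattan_distances(m)
      expect_equal(d, oracle_manhattan(m))
      expect_true(all(d >= 0))
      expect_equal(d, t(d))
      expect_equal(diag(d), setNames(rep(0, 8), rownames(m)))
      # triangle inequality
      for (i in 1:8) for (j in 1:8) for (k in 1:8)
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      # Hamming equivalence on 0/1 rows
      expect_equal(d[1, 2], sum(m[1, ] != m[2, ]))
    }
  })
})

test_that("hierarchical clustering merges identical cells first and matches
          hand agglomeration on 3 cells", {
  m <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1))
  hc <- hierarchical_cluster(m, "complete", "manhattan")
  expect_equal(hc$height[1], 0)  # identical pair joins at height 0
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))

  # hand computation: d(a,b)=1, d(a,c)=2, d(b,c)=3; complete linkage merges
  # (a,b) at 1, then c at max(2,3)=3
  m2 <- rbind(a = c(1, 0, 0), b = c(0, 0, 0), c = c(1, 1, 1))
  hc2 <- hierarchical_cluster(m2, "complete", "manhattan")
  expect_equal(hc2$height, c(1, 3))

  # permuting input rows preserves tree topology (cophenetic distances)
  perm <- c(3, 1, 2)
  hc3 <- hierarchical_cluster(m2[perm, ], "complete", "manhattan")
  co2 <- as.matrix(stats::cophenetic(hc2))
  co3 <- as.matrix(stats::cophenetic(hc3))
  expect_equal(co3[rownames(co2), colnames(co2)], co2)

  expect_error(hierarchical_cluster(m2[1, , drop = FALSE]), "2 rows")
})

test_that("dendrograms export as Newick readable by ape", {
  m <- rbind(a = c(1, 0, 0), b = c(0, 0, 0), c = c(1, 1, 1))
  nwk <- dendrogram_newick(hierarchical_cluster(m, "complete", "manhattan"))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})

test_that("Pearson correlation handles NA pairs and perfect (anti)
          correlation", {
  x <- c(1, 2, 3, 4, NA)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, x)$n, 4)
  expect_error(pearson_correlation(1:2, 2:1), "3 complete pairs")
  # log10 pairing drops non-positive pairs; remaining pairs are log-linear
  res <- pearson_correlation(c(10, 100, 1000, 0), c(2, 4, 8, 16), "log10")
  expect_equal(res$n, 3)
  expect_equal(res$r, 1)
})

test_that("circ_expression_table reproduces the fixture's hand-computed CGR
          and circRNA FPKM", {
  fx <- fixture_minimal()
  cons <- intersect_calls(fx$calls)
  tab <- circ_expression_table(cons, fx$expression, fx$cells)
  key <- paste(tab$cell_id, tab$circ_id)
  exp_key <- paste(fx$expected_circ_expression$cell_id,
                   fx$expected_circ_expression$circ_id)
  ord <- match(exp_key, key)
  expect_false(anyNA(ord))
  expect_equal(tab$cgr[ord], fx$expected_circ_expression$cgr)
  expect_equal(tab$circ_fpkm[ord], fx$expected_circ_expression$circ_fpkm)
})

test_that("quantities are invariant to circRNA relabeling and linear in
          junction reads", {
  expect_equal(compute_cgr(10L, 40L), 2 * compute_cgr(5L, 40L))
  expect_equal(compute_circ_fpkm(10L, 2, 5), 2 * compute_circ_fpkm(5L, 2, 5))
})

test_that("per-cell circRNA count t-test wrapper runs both contrasts", {
  m <- matrix(rbinom(8 * 30, 1, 0.3), nrow = 8,
              dimnames = list(paste0("c", 1:8), NULL))
  one <- circ_count_t_test(m, mu = 5)
  expect_s3_class(one, "htest")
  two <- circ_count_t_test(m, groups = rep(c("x", "y"), each = 4))
  expect_s3_class(two, "htest")
  expect_error(circ_count_t_test(m, groups = rep("x", 8)), "2 groups")
})
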