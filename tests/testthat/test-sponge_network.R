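# Seed-match scanning (linear and junction-spanning) and sponge-network
# assembly.

test_that("the miR-16 family seed AGCAGCA matches its reverse complement
          TGCTGCT as a 7mer-m8", {
  mirnas <- tibble::tibble(mirna_id = "hsa-miR-16",
                           sequence = "UAGCAGCACGUAAAUAUUGGCG")
  seq <- c(circX = "GGGGGTGCTGCTGGGGG")
  hits <- scan_seed_sites(seq, mirnas)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_start, 5L)
  expect_equal(hits$match_class, "7mer-m8")
  # with an A opposite position 1 the site upgrades to 8mer
  hits8 <- scan_seed_sites(c(circX = "GGGGGTGCTGCTAGGGG"), mirnas)
  expect_equal(hits8$match_class, "8mer")
  # no complementary 6mer anywhere -> empty
  expect_equal(nrow(scan_seed_sites(c(circY = "GGGGGGGGGG"), mirnas)), 0)
})

test_that("match counts are monotone non-increasing with stricter
          min_class and every reported site re-verifies", {
  fx <- fixture_minimal()
  withr::with_seed(41, {
    seqs <- setNames(vapply(1:5, function(i) random_dna_str(400),
                            character(1)), paste0("c", 1:5))
    counts <- vapply(c("6mer", "7mer-A1", "7mer-m8", "8mer"), function(mc)
      nrow(scan_seed_sites(seqs, fx$mirnas, mc)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    all_hits <- scan_seed_sites(seqs, fx$mirnas, "6mer")
    if (nrow(all_hits) > 0)
      expect_true(all(verify_seed_matches(all_hits, seqs, fx$mirnas)))
  })
})

test_that("random panels match the naive all-substring oracle", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      seqs <- setNames(vapply(1:3, function(i) random_dna_str(300),
                              character(1)), paste0("c", 1:3))
      mirnas <- tibble::tibble(
        mirna_id = paste0("m", 1:5),
        sequence = vapply(1:5, function(i) random_rna_str(22), character(1)))
      got <- scan_seed_sites(seqs, mirnas, "6mer")
      exp <- list()
      for (ci in names(seqs)) for (k in 1:5) {
        o <- oracle_seed_scan(seqs[[ci]], mirnas$sequence[k])
        if (nrow(o) > 0)
          exp[[length(exp) + 1]] <- cbind(circ_id = ci,
                                          mirna_id = mirnas$mirna_id[k], o)
      }
      exp <- if (length(exp) > 0) do.call(rbind, exp) else
        data.frame(circ_id = character(), mirna_id = character(),
                   site_start = integer(), match_class = character())
      keyify <- function(df) sort(paste(df$circ_id, df$mirna_id,
                                        df$site_start, df$match_class))
      expect_equal(keyify(got), keyify(exp))
    }
  })
})

test_that("junction-spanning sites are found on the circularized sequence
          only, with modular coordinates", {
  fx <- fixture_minimal()
  lin <- scan_seed_sites(fx$circ_seqs, fx$mirnas, "6mer")
  junc <- circ_junction_site_scan(fx$circ_seqs, fx$mirnas, "6mer")
  expect_equal(as.data.frame(junc),
               as.data.frame(fx$expected_junction_matches),
               ignore_attr = TRUE)
  # the wrapped site (split 4+3 across the junction) is absent linearly
  expect_false(any(lin$circ_id == fx$expected_junction_matches$circ_id &
                     lin$mirna_id == fx$expected_junction_matches$mirna_id))
  expect_true(all(verify_seed_matches(junc, fx$circ_seqs, fx$mirnas)))
})

test_that("the circular site set is rotation invariant", {
  fx <- fixture_minimal()
  rotate <- function(s, k) {
    L <- nchar(s)
    k <- k %% L
    if (k == 0) s else paste0(substr(s, k + 1, L), substr(s, 1, k))
  }
  withr::with_seed(43, {
    for (rep in 1:5) {
      base <- setNames(random_dna_str(200), "c1")
      k <- sample(1:199, 1)
      rot <- setNames(rotate(base[[1]], k), "c1")
      s0 <- scan_seed_sites_circular(base, fx$mirnas, "6mer")
      s1 <- scan_seed_sites_circular(rot, fx$mirnas, "6mer")
      expect_equal(nrow(s0), nrow(s1))
      shifted <- sort((s0$site_start - k) %% 200)
      expect_equal(shifted, sort(s1$site_start))
    }
  })
})

test_that("network counts follow the relational join; restriction prunes
          the gene layer only", {
  matches <- tibble::tibble(
    circ_id = c("circ1", "circ1"), mirna_id = c("m1", "m2"),
    site_start = c(0L, 10L), match_class = "7mer-m8")
  assoc <- tibble::tibble(mirna_id = c("m1", "m2"),
                          gene_id = c("geneA", "geneB"))
  g <- build_sponge_network(matches, assoc)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)

  g0 <- build_sponge_network(matches, assoc, restrict_genes = character())
  expect_equal(sum(igraph::V(g0)$type == "gene"), 0)
  expect_equal(igraph::ecount(g0), 2)   # circ-mir layer unchanged
  expect_equal(sum(igraph::V(g0)$type == "miRNA"), 2)

  # random join cardinalities equal the brute-force relational join
  withr::with_seed(44, {
    for (rep in 1:5) {
      sm <- tibble::tibble(
        circ_id = sample(paste0("c", 1:6), 30, TRUE),
        mirna_id = sample(paste0("m", 1:8), 30, TRUE),
        site_start = seq_len(30), match_class = "7mer-m8")
      tab <- tibble::tibble(
        mirna_id = sample(paste0("m", 1:10), 25, TRUE),
        gene_id = sample(paste0("g", 1:12), 25, TRUE))
      g <- build_sponge_network(sm, tab)
      cm_edges <- unique(paste(sm$circ_id, sm$mirna_id))
      mg_edges <- unique(paste(tab$mirna_id, tab$gene_id)[
        tab$mirna_id %in% sm$mirna_id])
      expect_equal(igraph::ecount(g), length(cm_edges) + length(mg_edges))
      nodes <- unique(c(sm$circ_id, sm$mirna_id,
                        tab$gene_id[tab$mirna_id %in% sm$mirna_id]))
      expect_equal(igraph::vcount(g), length(nodes))
      # bipartite typing: no circ-gene edges
      el <- igraph::as_edgelist(g)
      vt <- setNames(igraph::V(g)$type, igraph::V(g)$name)
      expect_false(any(vt[el[, 1]] == "circRNA" & vt[el[, 2]] == "gene"))
      expect_false(any(vt[el[, 1]] == "gene" & vt[el[, 2]] == "circRNA"))
    }
  })
})

test_that("top regulators rank by distinct circRNA degree with id
          tie-break", {
  sm <- tibble::tibble(
    circ_id = c(paste0("c", 1:10), "c1", "c1", "c2", "c3"),
    mirna_id = c(rep("mX", 10), "mA", "mB", "mB", "mB"),
    site_start = 0L, match_class = "7mer-m8")
  top <- top_regulator_mirnas(sm, k = 10)
  expect_equal(top$mirna_id[1], "mX")
  expect_equal(top$n_circ[1], 10L)
  expect_equal(top$mirna_id[2], "mB")   # 3 circs beats mA's 1
  expect_equal(nrow(top_regulator_mirnas(sm, k = 100)), 3)
  expect_equal(nrow(top_regulator_mirnas(sm[0, ], 5)), 0)
})
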