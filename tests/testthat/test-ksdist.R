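test_that("back-translation maps residues to codons and gaps to ---", {
  msa <- tibble::tibble(id = "g1", seq = "M-K")
  cds <- tibble::tibble(id = "g1", seq = "ATGAAA")
  expect_equal(backtranslate(msa, cds)$seq, "ATG---AAA")

  bad <- tibble::tibble(id = "g1", seq = "K-K")
  expect_error(backtranslate(bad, cds), "position 1")
})

test_that("back-translation round-trips a gap-free synthetic family", {
  set.seed(51)
  fam <- lapply(1:4, function(i) evolve_codon_pair(40, 0.3, seed = 50 + i))
  cds <- tibble::tibble(id = sprintf("g%d", 1:4),
                        seq = vapply(fam, `[[`, character(1), "seq_b"))
  msa <- tibble::tibble(id = cds$id,
                        seq = vapply(cds$seq, translate_cds, character(1),
                                     USE.NAMES = FALSE))
  codon_msa <- backtranslate(msa, cds)
  expect_equal(codon_msa$seq, cds$seq)
})

test_that("NG86 matches the closed-form single-difference example", {
  a <- strrep("GGT", 9)
  b <- paste0(strrep("GGT", 8), "GGC")
  est <- ks_ng86(a, b)
  # GGT's third position is fourfold degenerate: one synonymous site per codon
  expect_equal(est$S, 9)
  expect_equal(est$sd_count, 1)
  expect_equal(est$ps, 1 / 9)
  expect_equal(est$ks, -0.75 * log(1 - 4 / 27), tolerance = 1e-3)
  expect_equal(est$ka, 0)
})

test_that("NG86 is symmetric, zero on identity, and errors sensibly", {
  p <- evolve_codon_pair(80, 0.4, seed = 52)
  expect_identical(ks_ng86(p$seq_a, p$seq_b)$ks, ks_ng86(p$seq_b, p$seq_a)$ks)

  same <- ks_ng86(p$seq_a, p$seq_a)
  expect_equal(same$ks, 0)
  expect_equal(same$ka, 0)

  expect_error(ks_ng86("ATGAAA", "ATG"), "mismatch")
  expect_error(ks_ng86(strrep("ATG", 5), strrep("ATG", 5)), "synonymous")
})

test_that("NG86 flags saturation and preserves total site counts", {
  # GGT vs GGA at every codon: ps == 1 -> Jukes-Cantor undefined
  est <- ks_ng86(strrep("GGT", 9), strrep("GGA", 9))
  expect_true(est$saturated_ks)
  expect_true(is.na(est$ks))
  # S + N == 3 * codons on random pairs
  for (seed in 1:3) {
    p <- evolve_codon_pair(50, 0.5, seed = seed)
    est <- ks_ng86(p$seq_a, p$seq_b)
    expect_equal(est$S + est$N, 3 * 50, tolerance = 1e-6)
  }
})

test_that("NG86 recovers the generator's target divergence", {
  p <- evolve_codon_pair(300, 0.5, seed = 53)
  expect_lt(abs(ks_ng86(p$seq_a, p$seq_b)$ks - 0.5), 0.07)
})

test_that("UPGMA heights follow hand-computed merges with deterministic ties", {
  pair <- family_tree_alc(tibble::tibble(gene_a = "a", gene_b = "b", ks = 0.4))
  expect_equal(nrow(pair$merges), 1)
  expect_equal(pair$merges$height, 0.4)

  tri <- family_tree_alc(tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    ks = c(0.2, 1.0, 1.0)
  ))
  expect_equal(tri$merges$height, c(0.2, 1.0))
  expect_equal(tri$pair_nodes$node_id[tri$pair_nodes$gene_a == "a" &
                                        tri$pair_nodes$gene_b == "b"], "N01")

  # tie: all distances equal -> first merge is the lexicographically
  # smallest pair (a, b)
  tie <- family_tree_alc(tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"), ks = 1
  ))
  first <- tie$pair_nodes[tie$pair_nodes$node_id == "N01", ]
  expect_equal(c(first$gene_a, first$gene_b), c("a", "b"))
})

test_that("UPGMA agrees with the reference average-linkage implementation", {
  for (seed in c(61, 62, 63)) {
    pk <- rand_ks_pairs(8, seed)
    tree <- family_tree_alc(pk)
    ids <- sort(unique(c(pk$gene_a, pk$gene_b)))
    m <- matrix(0, 8, 8, dimnames = list(ids, ids))
    m[cbind(pk$gene_a, pk$gene_b)] <- pk$ks
    m <- m + t(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(tree$merges$height), sort(hc$height), tolerance = 1e-12)
  }
})

test_that("node weights sum to one per duplication event", {
  tri_pk <- tibble::tibble(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                           ks = c(0.2, 1.0, 1.2))
  tree <- family_tree_alc(tri_pk)
  nw <- deduplicate_ks(tree, tri_pk, mode = "node_weighted")
  root_rows <- nw[nw$node_id == "N02", ]
  expect_equal(root_rows$weight, c(0.5, 0.5))
  expect_equal(nw$weight[nw$node_id == "N01"], 1)

  na <- deduplicate_ks(tree, tri_pk, mode = "node_averaged")
  expect_equal(nrow(na), 2)            # one entry per internal node
  expect_equal(na$ks[na$node_id == "N02"], 1.1)
  expect_equal(na$weight, c(1, 1))
})

test_that("random family trees keep per-node weight sums at exactly one", {
  for (seed in 71:90) {
    n <- sample(3:16, 1)
    pk <- rand_ks_pairs(n, seed)
    tree <- family_tree_alc(pk)
    nw <- deduplicate_ks(tree, pk, mode = "node_weighted")
    sums <- tapply(nw$weight, nw$node_id, sum)
    expect_true(all(abs(sums - 1) <= 1e-12))
    # total weight equals the number of duplication nodes
    expect_equal(sum(nw$weight), n - 1, tolerance = 1e-12)
    na <- deduplicate_ks(tree, pk, mode = "node_averaged")
    expect_equal(nrow(na), n - 1)
  }
})

test_that("ortholog Ks estimates reflect the generator divergence", {
  set.seed(95)
  pairs <- lapply(1:10, function(i) evolve_codon_pair(200, 0.8, seed = 100 + i))
  cds_a <- tibble::tibble(id = sprintf("spA_%02d", 1:10),
                          seq = vapply(pairs, `[[`, character(1), "seq_a"))
  cds_b <- tibble::tibble(id = sprintf("spB_%02d", 1:10),
                          seq = vapply(pairs, `[[`, character(1), "seq_b"))
  rbh <- tibble::tibble(gene_a = cds_a$id, gene_b = cds_b$id)
  oks <- ortholog_ks(cds_a, cds_b, rbh)
  expect_equal(nrow(oks), 10)
  expect_lt(abs(mean(oks$ks) - 0.8), 0.05)

  self <- ortholog_ks(cds_a, cds_a, tibble::tibble(gene_a = cds_a$id,
                                                   gene_b = cds_a$id))
  expect_true(all(self$ks == 0))
  expect_equal(nrow(ortholog_ks(cds_a, cds_b, rbh[0, ])), 0)
})

test_that("trio decomposition follows the three-point closed form", {
  b <- trio_branch_ks(1.2, 1.0, 0.8)
  expect_equal(b$b_focal, 0.5)
  expect_equal(b$b_sister, 0.3)

  eq <- trio_branch_ks(1.0, 1.0, 0.8)
  expect_equal(eq$b_focal, eq$b_sister)
  expect_equal(eq$b_focal, 0.4)

  expect_warning(trio_branch_ks(0.1, 1.0, 0.2), "negative")
})

test_that("whole-distribution construction weights events once per node", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 0L, length_genes = 6L,
                        copies = 3L, ks = 0.4)
  g <- build_genome(1, 20, duplications = dup, seed = 97)
  ksd <- ks_distribution(g$families, g$cds, mode = "node_weighted")
  # 6 families of 3 genes -> 2 nodes each -> total weight 12
  expect_equal(sum(ksd$weight), 12, tolerance = 1e-12)
  sums <- tapply(ksd$weight, paste(ksd$family_id, ksd$node_id), sum)
  expect_true(all(abs(sums - 1) <= 1e-12))
})
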