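mk_hits <- function(proxy, bitscore) {
  n <- length(proxy)
  tibble::tibble(
    query = sprintf("q%04d", seq_len(n)), target = sprintf("t%04d", seq_len(n)),
    identity = 90, length = 100L, mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = 100L, tstart = 1L, tend = 100L,
    evalue = 1e-30, bitscore = bitscore,
    qlen = 100L, tlen = 100L, proxy_len = proxy, norm_score = NA_real_
  )
}

test_that("an exactly linear log-log relation is recovered and flattened", {
  proxy <- seq(1000, 100000, length.out = 500)
  res <- normalize_bitscores(mk_hits(proxy, bitscore = proxy), n_bins = 20)
  expect_equal(res$fit$slope, 1.0, tolerance = 1e-9)
  expect_equal(res$fit$intercept, 0.0, tolerance = 1e-9)
  expect_equal(res$hits$norm_score, rep(1, 500), tolerance = 1e-9)
})

test_that("length-independent bit-scores give slope zero and unit norm scores", {
  proxy <- seq(1000, 100000, length.out = 200)
  res <- normalize_bitscores(mk_hits(proxy, bitscore = rep(50, 200)),
                             n_bins = 10)
  expect_equal(res$fit$slope, 0.0, tolerance = 1e-12)
  expect_equal(res$hits$norm_score, rep(1, 200), tolerance = 1e-12)
})

test_that("a known power-law bias is recovered and removed on simulation", {
  h <- simulate_length_bias_hits(10000, exponent = 0.8, seed = 31)
  res <- normalize_bitscores(h)
  expect_lt(abs(res$fit$slope - 0.8), 0.05)
  expect_lt(res$fit$r_squared_all_after, 0.01)
  expect_gt(res$fit$r_squared_all_before, res$fit$r_squared_all_after)
})

test_that("normalization is scale-equivariant in the bit-scores", {
  h <- simulate_length_bias_hits(2000, seed = 32)
  a <- normalize_bitscores(h)
  h2 <- dplyr::mutate(h, bitscore = bitscore * 7.3)
  b <- normalize_bitscores(h2)
  expect_equal(a$hits$norm_score, b$hits$norm_score, tolerance = 1e-9)
})

test_that("degenerate proxy lengths fall back to geometric-mean scaling", {
  h <- mk_hits(rep(5000, 20), bitscore = exp(seq(3, 5, length.out = 20)))
  expect_warning(res <- normalize_bitscores(h), "proxy length")
  gm <- exp(mean(log(h$bitscore)))
  expect_equal(res$hits$norm_score, h$bitscore / gm)
})

test_that("n_bins larger than the hit count is clamped with a warning", {
  h <- mk_hits(seq(1000, 2000, length.out = 10), bitscore = seq(50, 80, length.out = 10))
  expect_warning(res <- normalize_bitscores(h, n_bins = 100), "clamped")
  expect_equal(res$fit$n_bins, 10)
})

test_that("Markov clustering separates disjoint cliques and isolated nodes", {
  ed <- tibble::tibble(
    gene_a = c("a", "a", "b", "x", "x", "y"),
    gene_b = c("b", "c", "c", "y", "z", "z"),
    weight = 1
  )
  fam <- markov_cluster(ed)
  expect_equal(length(unique(fam$family_id)), 2)
  expect_equal(unname(table(fam$family_id)), c(3L, 3L), ignore_attr = TRUE)

  solo <- markov_cluster(ed[0, ], nodes = "lonely")
  expect_equal(nrow(solo), 1)
  expect_true(solo$is_singleton)

  expect_error(markov_cluster(dplyr::mutate(ed, weight = -1)), "negative")
  expect_equal(nrow(markov_cluster(ed[0, ])), 0)
})

test_that("higher inflation fragments a path graph more", {
  path <- tibble::tibble(gene_a = letters[1:4], gene_b = letters[2:5],
                         weight = 1)
  k_low <- length(unique(markov_cluster(path, inflation = 1.2)$family_id))
  k_high <- length(unique(markov_cluster(path, inflation = 6)$family_id))
  expect_gt(k_high, k_low)
})

test_that("clusters never span disconnected components and partition the genes", {
  skip_if_not_installed("igraph")
  set.seed(41)
  genes <- sprintf("g%03d", 1:60)
  ed <- tibble::tibble(
    gene_a = sample(genes, 120, replace = TRUE),
    gene_b = sample(genes, 120, replace = TRUE),
    weight = runif(120, 0.5, 2)
  ) |> dplyr::filter(gene_a != gene_b)
  fam <- markov_cluster(ed, nodes = genes)
  # partition
  expect_setequal(fam$gene_id, genes)
  expect_equal(anyDuplicated(fam$gene_id), 0)
  # component oracle
  gr <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE,
                                      vertices = genes)
  comp <- igraph::components(gr)$membership
  crossing <- fam |>
    dplyr::mutate(comp = comp[gene_id]) |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(n_comp = dplyr::n_distinct(comp))
  expect_true(all(crossing$n_comp == 1))
})

test_that("reciprocal best hits match the worked examples and tie rule", {
  h <- tibble::tibble(
    query = c("a1", "a1", "a2"), target = c("b1", "b2", "b2"),
    bitscore = c(100, 90, 95), evalue = 1e-10
  )
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rbh <- reciprocal_best_hits(h, sp)
  expect_equal(rbh$gene_a, c("a1", "a2"))
  expect_equal(rbh$gene_b, c("b1", "b2"))

  tie <- tibble::tibble(query = c("a1", "a1"), target = c("b2", "b1"),
                        bitscore = 100, evalue = 1e-10)
  rbh2 <- reciprocal_best_hits(tie, sp)
  expect_equal(rbh2$gene_b, "b1")

  expect_equal(nrow(reciprocal_best_hits(h[0, ], sp)), 0)
})

test_that("RBH equals a brute-force double-argmax scan on a random matrix", {
  set.seed(42)
  a <- sprintf("a%02d", 1:20); b <- sprintf("b%02d", 1:20)
  scores <- matrix(runif(400, 10, 100), 20, 20, dimnames = list(a, b))
  h <- tidyr::expand_grid(query = a, target = b) |>
    dplyr::mutate(bitscore = scores[cbind(query, target)], evalue = 1e-10)
  sp <- setNames(c(rep("A", 20), rep("B", 20)), c(a, b))
  got <- reciprocal_best_hits(h, sp)
  want <- list()
  for (i in seq_along(a)) {
    j <- which.max(scores[i, ])
    if (which.max(scores[, j]) == i) {
      want[[length(want) + 1]] <- c(a[i], b[j])
    }
  }
  want <- do.call(rbind, want)
  expect_equal(got$gene_a, want[, 1])
  expect_equal(got$gene_b, want[, 2])
})

test_that("dating orthogroups require RBH coverage in every listed species", {
  anchors <- tibble::tibble(gene_a = "f1", gene_b = "f2")
  rbh <- list(
    sp1 = tibble::tibble(focal = c("f1", "f2"), other = c("s1a", "s1b")),
    sp2 = tibble::tibble(focal = "f1", other = "s2a"),
    sp3 = tibble::tibble(focal = "f2", other = "s3a")
  )
  og <- assemble_dating_orthogroups(anchors, rbh)
  expect_equal(length(unique(og$orthogroup_id)), 1)
  expect_setequal(og$gene_id, c("f1", "f2", "s1a", "s1b", "s2a", "s3a"))

  rbh$sp2 <- tibble::tibble(focal = character(), other = character())
  expect_equal(nrow(assemble_dating_orthogroups(anchors, rbh)), 0)
  relaxed <- assemble_dating_orthogroups(anchors, rbh, max_missing = 1)
  expect_equal(length(unique(relaxed$orthogroup_id)), 1)
})
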