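test_that("an implanted diagonal is recovered as exactly one segment", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 5L, length_genes = 10L,
                        copies = 2L, ks = 0.5)
  g <- build_genome(2, 40, duplications = dup, seed = 101)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_anchors, 10)
  truth <- g$segments_truth$anchors[[1]]
  got <- segs$anchors[[1]]
  expect_setequal(paste(pmin(got$gene_a, got$gene_b),
                        pmax(got$gene_a, got$gene_b)),
                  paste(pmin(truth$gene_a, truth$gene_b),
                        pmax(truth$gene_a, truth$gene_b)))
  expect_equal(nrow(detect_segments(g$loci, g$homolog_pairs[0, ])), 0)
})

test_that("inverted blocks are recovered in descending orientation", {
  loci <- dplyr::bind_rows(toy_loci("chr1", 20), toy_loci("chr2", 20))
  # anti-diagonal: gene i on chr1 pairs with gene (n + 1 - i) on chr2
  pairs <- tibble::tibble(
    gene_a = sprintf("chr1_g%03d", 3:10),
    gene_b = sprintf("chr2_g%03d", 12:5)
  )
  segs <- detect_segments(loci, pairs, loci_b = NULL, max_gap = 2)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_anchors, 8)
  expect_equal(segs$orientation, -1L)
  a <- segs$anchors[[1]]
  expect_true(all(diff(a$rank_a) > 0))
  expect_true(all(diff(a$rank_b) < 0))
})

test_that("anchors always lie inside their segment's rank intervals", {
  dup <- tibble::tibble(chromosome = c(1L, 2L), start_rank = c(2L, 6L),
                        length_genes = c(12L, 10L), copies = c(2L, 3L),
                        ks = c(0.8, 0.4))
  g <- build_genome(2, 40, duplications = dup, seed = 102)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  for (i in seq_len(nrow(segs))) {
    a <- segs$anchors[[i]]
    expect_true(all(a$rank_a >= segs$start_rank_a[i] &
                      a$rank_a <= segs$end_rank_a[i]))
    expect_true(all(a$rank_b >= segs$start_rank_b[i] &
                      a$rank_b <= segs$end_rank_b[i]))
  }
})

test_that("detection is invariant to chromosome relabeling and bp translation", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 4L, length_genes = 10L,
                        copies = 2L, ks = 0.5)
  g <- build_genome(2, 30, duplications = dup, seed = 103)
  base <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  relabeled <- g$loci |>
    dplyr::mutate(chromosome = paste0("scaffold_", chromosome),
                  start = start + 1234567L, end = end + 1234567L) |>
    index_ranks()
  moved <- detect_segments(relabeled, g$homolog_pairs, max_gap = 3)
  expect_equal(nrow(moved), nrow(base))
  expect_equal(moved$n_anchors, base$n_anchors)
  expect_equal(moved$anchors[[1]]$gene_a, base$anchors[[1]]$gene_a)
})

test_that("short segments are dropped by the base-pair length filter", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 2L, length_genes = 10L,
                        copies = 2L, ks = 0.5)
  g <- build_genome(1, 30, duplications = dup, seed = 104)
  # 10 genes at 20 kb spacing span ~180 kb: a 500 kb floor removes them
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3,
                          min_length_bp = 5e5)
  expect_equal(nrow(segs), 0)
})

test_that("dupstack assigns non-overlapping lanes, longest interval first", {
  segs <- tibble::tibble(
    segment_id = c("S1", "S2"),
    chrom_a = "chr1", start_rank_a = c(0L, 2L), end_rank_a = c(9L, 6L),
    chrom_b = c("chr2", "chr1"), start_rank_b = c(0L, 3L),
    end_rank_b = c(9L, 7L),
    start_bp_a = c(0L, 40000L), end_bp_a = c(200000L, 120000L),
    start_bp_b = c(0L, 60000L), end_bp_b = c(200000L, 140000L),
    n_anchors = c(10L, 5L), span_bp_a = c(200000L, 80000L),
    span_bp_b = c(200000L, 80000L), orientation = 1L, intra = TRUE,
    anchors = list(tibble::tibble(), tibble::tibble())
  )
  st <- dupstack(segs[1, ])
  expect_equal(unique(st$lane[st$chromosome == "chr1"]), 1L)
  st2 <- dupstack(segs)
  chr1 <- st2[st2$chromosome == "chr1", ]
  # three chr1 intervals: S1 side a, S2 both sides; overlaps force lanes
  expect_gt(max(chr1$lane), 1L)
  expect_equal(chr1$lane[which.max(chr1$end_bp - chr1$start_bp)], 1L)
})

test_that("syndepth reports the implanted multiplication levels", {
  dup2 <- tibble::tibble(chromosome = 1L, start_rank = 2L, length_genes = 10L,
                         copies = 2L, ks = 0.5)
  g2 <- build_genome(2, 40, duplications = dup2, seed = 105)
  s2 <- syndepth(detect_segments(g2$loci, g2$homolog_pairs, max_gap = 3))
  expect_equal(s2$level, 2L)
  expect_equal(s2$n_groups, 1L)

  dup3 <- dplyr::mutate(dup2, copies = 3L)
  g3 <- build_genome(3, 40, duplications = dup3, seed = 106)
  s3 <- syndepth(detect_segments(g3$loci, g3$homolog_pairs, max_gap = 3))
  expect_equal(s3$level, 3L)
  expect_equal(s3$n_groups, 1L)

  both <- tibble::tibble(chromosome = c(1L, 2L), start_rank = c(2L, 20L),
                         length_genes = c(10L, 12L), copies = c(2L, 3L),
                         ks = c(0.5, 0.3))
  gb <- build_genome(3, 60, duplications = both, seed = 107)
  sb <- syndepth(detect_segments(gb$loci, gb$homolog_pairs, max_gap = 3))
  expect_equal(sb$n_groups[match(c(2L, 3L), sb$level)], c(1L, 1L))
})

test_that("dot-plot records count every homolog pair and flag every anchor", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 3L, length_genes = 10L,
                        copies = 2L, ks = 0.6)
  g <- build_genome(2, 30, duplications = dup, seed = 108)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  dots <- dotplot_table(g$loci, g$loci, g$homolog_pairs,
                        anchor_set = segment_anchors(segs))
  expect_equal(nrow(dots), nrow(g$homolog_pairs))
  expect_equal(sum(dots$is_anchor), sum(segs$n_anchors))

  one <- dotplot_table(toy_loci("c1", 5), toy_loci("c1", 5),
                       tibble::tibble(gene_a = "c1_g002", gene_b = "c1_g004"))
  expect_equal(one$x, 1)
  expect_equal(one$y, 3)

  with_ks <- dotplot_table(g$loci, g$loci, g$homolog_pairs,
                           anchor_set = segment_anchors(segs),
                           ks_lookup = tibble::tibble(
                             gene_a = g$homolog_pairs$gene_a[1],
                             gene_b = g$homolog_pairs$gene_b[1], ks = 0.7))
  expect_equal(with_ks$ks[1], 0.7)
})

test_that("anchor Ks distributions sit at the implanted age", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 2L, length_genes = 20L,
                        copies = 2L, ks = 1.0)
  g <- build_genome(2, 50, duplications = dup, seed = 109)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  ak <- anchor_ks(segs, cds = g$cds)
  expect_equal(nrow(ak), 20)
  expect_true(all(ak$weight == 1))
  expect_lt(abs(kde_mode(ak$ks, ak$weight) - 1.0), 0.05)

  expect_equal(nrow(anchor_ks(segs[0, ], cds = g$cds)), 0)
})

test_that("triplicated anchors contribute all pairwise relations", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 2L, length_genes = 12L,
                        copies = 3L, ks = 0.5)
  g <- build_genome(3, 40, duplications = dup, seed = 110)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  expect_equal(nrow(segs), choose(3, 2))
  ak <- anchor_ks(segs, cds = g$cds)
  # 12 anchor families of 3 -> 2 duplication nodes each
  expect_equal(sum(ak$weight), 24, tolerance = 1e-12)
})

test_that("anchor precision stays high under sparse random background pairs", {
  dup <- tibble::tibble(chromosome = c(1L, 2L), start_rank = c(2L, 4L),
                        length_genes = 12L, copies = 2L, ks = 0.5)
  g <- build_genome(2, 60, duplications = dup, seed = 111)
  set.seed(112)
  n_genes <- nrow(g$loci)
  n_noise <- ceiling(0.001 * n_genes^2 / 2)
  noise <- tibble::tibble(
    gene_a = sample(g$loci$gene_id, n_noise, replace = TRUE),
    gene_b = sample(g$loci$gene_id, n_noise, replace = TRUE)
  ) |> dplyr::filter(gene_a != gene_b)
  segs <- detect_segments(g$loci, dplyr::bind_rows(g$homolog_pairs, noise),
                          max_gap = 3)
  truth <- g$segments_truth |>
    dplyr::pull(anchors) |>
    dplyr::bind_rows()
  truth_keys <- paste(pmin(truth$gene_a, truth$gene_b),
                      pmax(truth$gene_a, truth$gene_b))
  got <- segment_anchors(segs)
  got_keys <- paste(got$gene_a, got$gene_b)
  precision <- mean(got_keys %in% truth_keys)
  recall <- mean(truth_keys %in% got_keys)
  expect_gte(precision, 0.95)
  expect_equal(recall, 1.0)
})

test_that("segment tables round-trip through the TSV import path", {
  dup <- tibble::tibble(chromosome = 1L, start_rank = 2L, length_genes = 10L,
                        copies = 2L, ks = 0.5)
  g <- build_genome(2, 30, duplications = dup, seed = 113)
  segs <- detect_segments(g$loci, g$homolog_pairs, max_gap = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_segments_tsv(segs, f)
  back <- read_segments_tsv(f)
  expect_equal(back$segment_id, segs$segment_id)
  expect_equal(back$n_anchors, segs$n_anchors)
  expect_setequal(paste(back$anchors[[1]]$gene_a, back$anchors[[1]]$gene_b),
                  paste(segs$anchors[[1]]$gene_a, segs$anchors[[1]]$gene_b))
})
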