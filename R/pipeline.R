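#' Run the full synthetic-to-peak WGD pipeline
#'
#' Generates a synthetic genome with an implanted WGD, writes its FASTA/GFF3
#' and hit-table inputs, then runs the analysis chain: bit-score
#' normalization and Markov clustering (paranome), the node-weighted Ks age
#' distribution, collinear-segment detection with dupstack/syndepth/dot-plot
#' summaries, the anchor-pair Ks distribution, and a log-scale GMM fit of the
#' anchor Ks peak. All tables are written as TSV to `outdir` together with a
#' JSON manifest (parameters, seed, output checksums).
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param n_chromosomes,genes_per_chromosome Genome size. Defaults 2 and 300.
#' @param wgd_ks Target Ks of the implanted WGD. Default 1.
#' @param segment_genes Genes per implanted duplicated run. Default 40.
#' @param n_codons Codons per gene. Default 100.
#' @param inflation MCL inflation. Default 2.
#' @param max_gap,min_genes,min_length_bp Collinearity parameters (defaults
#'   5, 3, 100000).
#' @param mode Ks redundancy-removal mode. Default `"node_weighted"`.
#' @return An object of class `ksage_pipeline`: the genome, families,
#'   normalization fit, Ks distribution, segments, syndepth profile, anchor
#'   Ks, the selected anchor-peak mixture fit, and the manifest path.
#' @export
run_wgd_pipeline <- function(outdir, seed = 42, n_chromosomes = 2,
                             genes_per_chromosome = 300, wgd_ks = 1,
                             segment_genes = 40, n_codons = 100,
                             inflation = 2, max_gap = 5, min_genes = 3,
                             min_length_bp = 100000,
                             mode = c("node_weighted", "node_averaged")) {
  mode <- match.arg(mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  # one WGD: every chromosome contributes one duplicated run
  dup <- tibble(
    chromosome = seq_len(n_chromosomes),
    start_rank = 10L,
    length_genes = segment_genes,
    copies = 2L,
    ks = wgd_ks
  )
  genome <- build_genome(n_chromosomes, genes_per_chromosome,
                         duplications = dup, n_codons = n_codons)
  paths <- list(
    cds = file.path(outdir, "cds.fasta"),
    gff = file.path(outdir, "genes.gff3"),
    hits = file.path(outdir, "hits.tsv")
  )
  write_fasta(genome$cds, paths$cds)
  write_gff_genes(genome$loci, paths$gff)
  hits0 <- synthetic_hits(genome)
  write_hits(hits0, paths$hits)
  # dmd: read inputs back through the standard readers
  cds <- read_fasta(paths$cds)
  loci <- read_gff_genes(paths$gff)
  lengths <- setNames(nchar(cds$seq) %/% 3L, cds$id)
  hits <- read_hits(paths$hits, lengths)
  norm <- normalize_bitscores(hits)
  families <- markov_cluster(
    norm$hits |> transmute(gene_a = .data$query, gene_b = .data$target,
                           weight = .data$norm_score),
    inflation = inflation, nodes = cds$id
  )
  # ksd
  ksd <- ks_distribution(families, cds, mode = mode)
  # syn
  pairs <- families |>
    group_by(.data$family_id) |>
    filter(dplyr::n() >= 2) |>
    summarise(p = list({
      cmb <- utils::combn(sort(.data$gene_id), 2)
      tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
    }), .groups = "drop") |>
    tidyr::unnest("p") |>
    select("gene_a", "gene_b")
  segments <- detect_segments(loci, pairs, max_gap = max_gap,
                              min_genes = min_genes,
                              min_length_bp = min_length_bp)
  depth <- syndepth(segments)
  anchors <- segment_anchors(segments)
  ks_lookup <- ksd |>
    filter(!is.na(.data$gene_a)) |>
    select("gene_a", "gene_b", "ks")
  dots <- dotplot_table(loci, loci, pairs, anchor_set = anchors,
                        ks_lookup = ks_lookup)
  stack <- dupstack(segments)
  aks <- anchor_ks(segments, ks_estimates = ks_lookup, cds = cds, mode = mode)
  # peak
  fits <- fit_gmm_log(aks, k_range = 1, seed = seed)
  peak_fit <- select_model(fits)
  outputs <- list(
    families = file.path(outdir, "families.tsv"),
    normalization = file.path(outdir, "normalization.tsv"),
    ks_distribution = file.path(outdir, "ks_distribution.tsv"),
    segments = file.path(outdir, "segments.tsv"),
    syndepth = file.path(outdir, "syndepth.tsv"),
    dotplot = file.path(outdir, "dotplot.tsv"),
    dupstack = file.path(outdir, "dupstack.tsv"),
    anchor_ks = file.path(outdir, "anchor_ks.tsv"),
    peak_fit = file.path(outdir, "peak_fit.tsv")
  )
  write_table_tsv(families, outputs$families)
  write_table_tsv(as_tibble(glance(norm$fit)), outputs$normalization)
  write_table_tsv(ksd, outputs$ks_distribution)
  write_segments_tsv(segments, outputs$segments)
  write_table_tsv(depth, outputs$syndepth)
  write_table_tsv(dots, outputs$dotplot)
  write_table_tsv(stack, outputs$dupstack)
  write_table_tsv(aks, outputs$anchor_ks)
  write_table_tsv(tidy(peak_fit), outputs$peak_fit)
  manifest <- list(
    seed = seed,
    parameters = list(
      n_chromosomes = n_chromosomes,
      genes_per_chromosome = genes_per_chromosome,
      wgd_ks = wgd_ks, segment_genes = segment_genes, n_codons = n_codons,
      inflation = inflation, max_gap = max_gap, min_genes = min_genes,
      min_length_bp = min_length_bp, mode = mode
    ),
    inputs = purrr::map_chr(paths, identity),
    outputs = purrr::map_chr(outputs, identity),
    checksums = as.list(tools::md5sum(unlist(outputs)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(list(
    genome = genome, families = families, normalization = norm$fit,
    ks_distribution = ksd, segments = segments, syndepth = depth,
    dotplot = dots, dupstack = stack, anchor_ks = aks,
    peak_fit = peak_fit, outputs = outputs, manifest = manifest_path
  ), class = "ksage_pipeline")
}

#' @export
print.ksage_pipeline <- function(x, ...) {
  cat("ksage pipeline run\n")
  cat(sprintf("  %d genes in %d families (%d multi-gene)\n",
              nrow(x$families), length(unique(x$families$family_id)),
              sum(!x$families$is_singleton)))
  cat(sprintf("  %d collinear segment(s), %d anchor Ks value(s)\n",
              nrow(x$segments), nrow(x$anchor_ks)))
  if (nrow(x$peak_fit$components) > 0) {
    cat(sprintf("  anchor-Ks peak at Ks = %.3f\n", x$peak_fit$components$peak[1]))
  }
  cat(sprintf("  manifest: %s\n", x$manifest))
  invisible(x)
}
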