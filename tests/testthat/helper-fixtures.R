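# shared fixtures, all generated in code

# minimal loci tibble with dense ranks, one gene every 20 kb
toy_loci <- function(chrom, n, gene_bp = 300, spacing = 20000,
                     prefix = chrom) {
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", prefix, seq_len(n)),
    chromosome = chrom,
    start = (seq_len(n) - 1L) * spacing,
    end = (seq_len(n) - 1L) * spacing + gene_bp,
    strand = "+"
  ) |> ksage::index_ranks()
}

# random symmetric Ks "matrix" as a pair tibble over n leaves
rand_ks_pairs <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  cmb <- utils::combn(ids, 2)
  tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ],
                 ks = stats::runif(ncol(cmb), 0.05, 2))
}

# stub bootstrap-mode object with prescribed replicate vector
boot_stub <- function(modes) {
  structure(list(modes = modes, mean_mode = mean(modes),
                 sd_mode = stats::sd(modes),
                 ci90 = unname(stats::quantile(modes, c(.05, .95))),
                 raw_mode = mean(modes), n_boot = length(modes)),
            class = "ksage_boot")
}

# lognormal ortholog-Ks sample whose density mode sits at `mode_at`
ortholog_sample <- function(mode_at, n = 1000, sdlog = 0.2) {
  stats::rlnorm(n, meanlog = log(mode_at) + sdlog^2, sdlog = sdlog)
}
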