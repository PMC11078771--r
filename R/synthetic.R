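#' Specify an exponential + lognormal Ks mixture
#'
#' The background of small-scale duplications is exponential on the Ks scale;
#' WGD peaks are lognormal. Component weights plus the background weight must
#' sum to 1.
#'
#' @param exp_rate Rate of the exponential background (per Ks unit).
#' @param exp_weight Weight of the background in `[0, 1]`.
#' @param components Tibble with columns `weight`, `log_mean`, `log_sd`
#'   (one row per lognormal peak), or `NULL` for background only.
#' @param ks_max Truncation point: samples above it are redrawn. Default 5.
#' @return An object of class `ksage_mixture_spec`.
#' @export
mixture_spec <- function(exp_rate, exp_weight = 1, components = NULL,
                         ks_max = 5) {
  if (is.null(components)) {
    components <- tibble(weight = numeric(), log_mean = numeric(),
                         log_sd = numeric())
  }
  components <- as_tibble(components)
  w <- c(exp_weight, components$weight)
  if (abs(sum(w) - 1) > 1e-9) {
    abort(paste0("mixture weights must sum to 1, got ", sum(w)))
  }
  if (any(w < 0) || (nrow(components) > 0 && any(components$log_sd <= 0))) {
    abort("invalid mixture spec: negative weight or non-positive log_sd")
  }
  if (exp_rate <= 0) abort("exp_rate must be positive")
  structure(list(exp_rate = exp_rate, exp_weight = exp_weight,
                 components = components, ks_max = ks_max),
            class = "ksage_mixture_spec")
}

#' Sample Ks values from a mixture specification
#'
#' Component origin labels are kept alongside the values so parameter-recovery
#' tests have a ground truth; fitting code must never see them.
#'
#' @param spec A [mixture_spec()].
#' @param n Number of draws.
#' @param seed Integer seed for reproducibility.
#' @return A tibble `ks`, `component` (`"background"` or `"lognormal_<i>"`).
#' @export
sample_ks <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ksage_mixture_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(spec$components)
  labels <- c("background", if (m > 0) paste0("lognormal_", seq_len(m)))
  probs <- c(spec$exp_weight, spec$components$weight)
  draw <- function(k) {
    comp <- sample.int(m + 1, k, replace = TRUE, prob = probs)
    x <- numeric(k)
    bg <- comp == 1
    x[bg] <- rexp(sum(bg), rate = spec$exp_rate)
    for (j in seq_len(m)) {
      sel <- comp == j + 1
      x[sel] <- rlnorm(sum(sel), meanlog = spec$components$log_mean[j],
                       sdlog = spec$components$log_sd[j])
    }
    tibble(ks = x, component = labels[comp])
  }
  out <- draw(n)
  over <- which(out$ks > spec$ks_max)
  while (length(over) > 0) {
    out[over, ] <- draw(length(over))
    over <- which(out$ks > spec$ks_max)
  }
  out
}

#' Evolve a codon sequence pair to a target synonymous divergence
#'
#' Generates a random stop-free CDS of `n_codons` codons, then derives a
#' second copy by repeatedly applying single-nucleotide substitutions drawn
#' uniformly over the synonymous options of the current sequence, until the
#' NG86 Ks of the pair reaches `target_ks` (within one substitution). The
#' protein translation is never changed and stop codons are never created.
#'
#' @param n_codons Number of codons (at least 10).
#' @param target_ks Target NG86 Ks; must not exceed `saturation_guard`.
#' @param seed Integer seed.
#' @param saturation_guard Upper bound on reachable targets. Default 3.
#' @return A list: `seq_a`, `seq_b`, `n_substitutions` (synonymous
#'   substitutions applied), `realized_ks`.
#' @export
evolve_codon_pair <- function(n_codons, target_ks, seed = NULL,
                              saturation_guard = 3) {
  stopifnot(n_codons >= 10, target_ks >= 0)
  if (target_ks > saturation_guard) {
    abort(paste0("target_ks ", target_ks, " exceeds the saturation guard (",
                 saturation_guard, ")"))
  }
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_tables()
  # favour codons with synonymous options so small families stay evolvable
  pool <- tab$non_stop
  codons_a <- sample(pool, n_codons, replace = TRUE)
  ia <- unname(tab$idx[codons_a])
  ib <- ia
  # per-codon state for incremental NG86
  S_a <- sum(tab$syn_sites[ia])
  n_subs <- 0L
  ks_now <- 0
  max_steps <- 1000L * n_codons
  while (ks_now < target_ks) {
    n_opts <- lengths(tab$syn_neighbors[ib])
    total <- sum(n_opts)
    if (total == 0) abort("too few synonymous sites to reach target_ks")
    pos <- sample.int(length(ib), 1, prob = n_opts)
    nb <- tab$syn_neighbors[[ib[pos]]]
    ib[pos] <- unname(tab$idx[nb[sample.int(length(nb), 1)]])
    n_subs <- n_subs + 1L
    S <- (S_a + sum(tab$syn_sites[ib])) / 2
    sd_count <- sum(tab$sd_mat[cbind(ia, ib)])
    ps <- sd_count / S
    arg <- 1 - 4 / 3 * ps
    if (arg <= 0 || n_subs >= max_steps) {
      abort(paste0("target_ks ", target_ks,
                   " unreachable: synonymous divergence saturated"))
    }
    ks_now <- -3 / 4 * log(arg)
  }
  list(
    seq_a = paste(tab$codons[ia], collapse = ""),
    seq_b = paste(tab$codons[ib], collapse = ""),
    n_substitutions = n_subs,
    realized_ks = ks_now
  )
}

#' Build a synthetic genome with implanted collinear duplications
#'
#' Lays out `genes_per_chromosome` single-copy genes per chromosome (random
#' stop-free CDS), then implants duplicated gene runs: for each requested
#' duplication, `copies - 1` extra copies of a source run are appended to the
#' ends of (cyclically chosen) chromosomes, each gene evolved to the
#' requested Ks against its source. Ground truth (families, homeologous
#' relations with realized per-anchor Ks) is recorded for testing.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Single-copy genes laid out per chromosome.
#' @param duplications Tibble with columns `chromosome` (integer index),
#'   `start_rank` (0-based), `length_genes`, `copies` (total copy number,
#'   2 = duplication, 3 = triplication), `ks` (target Ks per copy). `NULL`
#'   for no implants.
#' @param n_codons Typical codons per gene; per-gene lengths are drawn
#'   uniformly from `[0.5, 1.5] * n_codons` (minimum 10). Default 100.
#' @param gene_spacing_bp Base-pair spacing between gene starts. Default 20000.
#' @param seed Integer seed.
#' @return An object of class `ksage_genome`: `loci`, `cds`, `families`
#'   (ground-truth partition), `segments_truth` (one row per homeologous
#'   relation: `relation_id`, `copies`, `anchors` list-column with realized
#'   Ks), `homolog_pairs` (all true within-family pairs).
#' @export
build_genome <- function(n_chromosomes, genes_per_chromosome,
                         duplications = NULL, n_codons = 100,
                         gene_spacing_bp = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_tables()
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  gene_order <- vector("list", n_chromosomes)
  names(gene_order) <- chroms
  cds <- list()
  len_lo <- max(10L, as.integer(round(0.5 * n_codons)))
  len_hi <- as.integer(round(1.5 * n_codons))
  for (c_i in seq_len(n_chromosomes)) {
    ids <- sprintf("%s_g%04d", chroms[c_i], seq_len(genes_per_chromosome))
    gene_order[[c_i]] <- ids
    for (id in ids) {
      len <- sample(len_lo:len_hi, 1)
      cds[[id]] <- paste(sample(tab$non_stop, len, replace = TRUE),
                         collapse = "")
    }
  }
  families <- tibble(family_id = paste0("TF", seq_along(unlist(gene_order))),
                     gene_id = unlist(gene_order, use.names = FALSE))
  fam_of <- setNames(families$family_id, families$gene_id)
  segments_truth <- list()
  if (!is.null(duplications) && nrow(duplications) > 0) {
    duplications <- as_tibble(duplications)
    # overlap check on source runs
    ivs <- duplications |>
      mutate(end_rank = .data$start_rank + .data$length_genes - 1L)
    for (c_i in unique(ivs$chromosome)) {
      sub <- ivs |> filter(.data$chromosome == c_i) |> arrange(.data$start_rank)
      if (nrow(sub) > 1 &&
          any(sub$start_rank[-1] <= sub$end_rank[-nrow(sub)])) {
        abort("overlapping duplication implants requested")
      }
      if (any(sub$end_rank >= genes_per_chromosome)) {
        abort("duplication implant does not fit within its chromosome")
      }
    }
    for (d in seq_len(nrow(duplications))) {
      du <- duplications[d, ]
      src_chr <- du$chromosome
      src <- gene_order[[src_chr]][du$start_rank + seq_len(du$length_genes)]
      copy_runs <- list(src)
      for (k in seq_len(du$copies - 1)) {
        tgt_chr <- ((src_chr - 1L + k) %% n_chromosomes) + 1L
        run_ids <- sprintf("%s_d%dc%d_%03d", chroms[src_chr], d, k,
                           seq_len(du$length_genes))
        for (g in seq_along(src)) {
          ev <- evolve_codon_pair_from(cds[[src[g]]], du$ks)
          cds[[run_ids[g]]] <- ev$seq_b
        }
        gene_order[[tgt_chr]] <- c(gene_order[[tgt_chr]], run_ids)
        copy_runs[[k + 1]] <- run_ids
      }
      # families: source + copies
      for (g in seq_along(src)) {
        extra <- vapply(copy_runs[-1], `[`, character(1), g)
        families <- bind_rows(
          families,
          tibble(family_id = fam_of[[src[g]]], gene_id = extra)
        )
      }
      # pairwise homeologous relations among copies
      cmb <- utils::combn(seq_along(copy_runs), 2)
      for (p in seq_len(ncol(cmb))) {
        ra <- copy_runs[[cmb[1, p]]]
        rb <- copy_runs[[cmb[2, p]]]
        anchors <- purrr::map2(ra, rb, function(a, b) {
          ks_ng86(cds[[a]], cds[[b]], a, b)[, c("gene_a", "gene_b", "ks")]
        }) |> purrr::list_rbind()
        segments_truth[[length(segments_truth) + 1]] <- tibble(
          relation_id = sprintf("dup%d_rel%d", d, p),
          duplication = d, copies = du$copies,
          anchors = list(anchors)
        )
      }
    }
  }
  loci <- purrr::imap(gene_order, function(ids, chr) {
    tibble(
      gene_id = ids, chromosome = chr,
      start = (seq_along(ids) - 1L) * gene_spacing_bp,
      end = (seq_along(ids) - 1L) * gene_spacing_bp +
        nchar(unlist(cds[ids], use.names = FALSE)),
      strand = "+"
    )
  }) |> purrr::list_rbind() |> index_ranks()
  cds_tbl <- tibble(id = names(cds), seq = unlist(cds, use.names = FALSE)) |>
    arrange(.data$id)
  fam_sizes <- families |> count(.data$family_id)
  multi <- families |>
    inner_join(filter(fam_sizes, .data$n >= 2), by = "family_id")
  homolog_pairs <- if (nrow(multi) > 0) {
    split(multi$gene_id, multi$family_id) |>
      purrr::map(function(g) {
        cmb <- utils::combn(sort(g), 2)
        tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
      }) |>
      purrr::list_rbind()
  } else {
    tibble(gene_a = character(), gene_b = character())
  }
  structure(list(
    loci = loci, cds = cds_tbl, families = arrange(families, .data$family_id,
                                                   .data$gene_id),
    segments_truth = purrr::list_rbind(segments_truth),
    homolog_pairs = homolog_pairs,
    n_codons = n_codons
  ), class = "ksage_genome")
}

# evolve a copy of an existing CDS to a target Ks (uses the ambient RNG
# stream; seed handling belongs to the caller)
evolve_codon_pair_from <- function(seq_a, target_ks) {
  tab <- codon_tables()
  ia <- codon_indices(seq_a)
  if (anyNA(ia)) abort("source CDS contains stop or ambiguous codons")
  ib <- ia
  S_a <- sum(tab$syn_sites[ia])
  ks_now <- 0
  n_subs <- 0L
  max_steps <- 1000L * length(ia)
  while (ks_now < target_ks) {
    n_opts <- lengths(tab$syn_neighbors[ib])
    pos <- sample.int(length(ib), 1, prob = n_opts)
    nb <- tab$syn_neighbors[[ib[pos]]]
    ib[pos] <- unname(tab$idx[nb[sample.int(length(nb), 1)]])
    n_subs <- n_subs + 1L
    S <- (S_a + sum(tab$syn_sites[ib])) / 2
    ps <- sum(tab$sd_mat[cbind(ia, ib)]) / S
    arg <- 1 - 4 / 3 * ps
    if (arg <= 0 || n_subs >= max_steps) {
      abort("target Ks unreachable for implant sequence")
    }
    ks_now <- -3 / 4 * log(arg)
  }
  list(seq_b = paste(tab$codons[ib], collapse = ""), realized_ks = ks_now,
       n_substitutions = n_subs)
}

#' Simulate an all-vs-all hit table for a synthetic genome
#'
#' Emits one 12-column-style hit per true homolog pair, with bit-scores
#' following a power law in the proxy gene length times lognormal noise
#' (the gene-length bias the normalization step removes).
#'
#' @param genome A [build_genome()] result.
#' @param exponent Power-law exponent of bit-score in proxy length.
#' @param noise_sdlog Lognormal noise sd (log scale). Default 0.1.
#' @param seed Integer seed.
#' @return A hits tibble in the shape returned by [read_hits()].
#' @export
synthetic_hits <- function(genome, exponent = 0.8, noise_sdlog = 0.1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aalen <- setNames(nchar(genome$cds$seq) %/% 3L, genome$cds$id)
  pairs <- genome$homolog_pairs
  n <- nrow(pairs)
  qlen <- unname(aalen[pairs$gene_a])
  tlen <- unname(aalen[pairs$gene_b])
  proxy <- as.numeric(qlen) * as.numeric(tlen)
  bitscore <- proxy^exponent * rlnorm(n, 0, noise_sdlog)
  tibble(
    query = pairs$gene_a, target = pairs$gene_b,
    identity = 90, length = pmin(qlen, tlen), mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = qlen, tstart = 1L, tend = tlen,
    evalue = 1e-50, bitscore = bitscore,
    qlen = qlen, tlen = tlen, proxy_len = proxy, norm_score = NA_real_
  )
}

#' Simulate a standalone gene-length-biased hit table
#'
#' Independent of any genome: hits with random amino-acid lengths and
#' bit-scores `proxy_len^exponent * lognormal noise`, used to exercise the
#' bit-score normalization on a known power law.
#'
#' @param n Number of hits.
#' @param exponent True power-law exponent. Default 0.8.
#' @param noise_sdlog Lognormal noise sd (log scale). Default 0.2.
#' @param len_range Amino-acid length range to draw from.
#' @param seed Integer seed.
#' @return A hits tibble in the shape returned by [read_hits()].
#' @export
simulate_length_bias_hits <- function(n, exponent = 0.8, noise_sdlog = 0.2,
                                      len_range = c(100L, 2000L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qlen <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  tlen <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  proxy <- as.numeric(qlen) * as.numeric(tlen)
  ids <- sprintf("s%06d", seq_len(2 * n))
  tibble(
    query = ids[seq_len(n)], target = ids[n + seq_len(n)],
    identity = 90, length = pmin(qlen, tlen), mismatches = 0L, gapopens = 0L,
    qstart = 1L, qend = qlen, tstart = 1L, tend = tlen,
    evalue = 1e-50, bitscore = proxy^exponent * rlnorm(n, 0, noise_sdlog),
    qlen = qlen, tlen = tlen, proxy_len = proxy, norm_score = NA_real_
  )
}
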