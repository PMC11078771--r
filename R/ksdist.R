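#' NG86 pairwise Ks and Ka estimate
#'
#' Counts synonymous and nonsynonymous sites per codon by the
#' fractional-site method of Nei and Gojobori (1986), averaged over the two
#' sequences, counts differences averaged over all minimal substitution paths
#' (paths crossing stop codons excluded), and applies the Jukes-Cantor
#' correction `ks = -3/4 * log(1 - 4/3 * ps)`. Codon sites where either codon
#' contains an ambiguous base or is a stop codon are skipped and excluded
#' from the site counts. The estimate is flagged saturated when the
#' Jukes-Cantor argument is non-positive (`ps >= 0.75`).
#'
#' @param codon_a,codon_b Gap-free coding sequences of equal length
#'   (multiple of 3).
#' @param gene_a,gene_b Optional gene ids carried into the output.
#' @return A one-row tibble: `gene_a`, `gene_b`, `S`, `N`, `sd_count`,
#'   `nd_count`, `ps`, `pn`, `ks`, `ka`, `saturated_ks`, `saturated_ka`.
#'   `ks`/`ka` are `NA` when saturated.
#' @export
ks_ng86 <- function(codon_a, codon_b, gene_a = "a", gene_b = "b") {
  if (nchar(codon_a) != nchar(codon_b)) {
    abort("sequence length mismatch in ks_ng86")
  }
  tab <- codon_tables()
  ia <- codon_indices(toupper(codon_a))
  ib <- codon_indices(toupper(codon_b))
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * length(ia) - S
  if (S <= 0) abort("zero synonymous sites in ks_ng86")
  sd_count <- sum(tab$sd_mat[cbind(ia, ib)])
  nd_count <- sum(tab$nd_mat[cbind(ia, ib)])
  ps <- sd_count / S
  pn <- nd_count / N
  jc <- function(p) {
    arg <- 1 - 4 / 3 * p
    if (arg <= 0) NA_real_ else -3 / 4 * log(arg)
  }
  ks <- jc(ps); ka <- jc(pn)
  tibble(
    gene_a = gene_a, gene_b = gene_b,
    S = S, N = N, sd_count = sd_count, nd_count = nd_count,
    ps = ps, pn = pn, ks = ks, ka = ka,
    saturated_ks = is.na(ks), saturated_ka = is.na(ka)
  )
}

#' Pairwise NG86 Ks for a set of gene pairs
#'
#' @param cds A tibble of coding sequences (`id`, `seq`).
#' @param pairs A tibble with columns `gene_a`, `gene_b`; if `NULL`, all
#'   pairs among the sequences in `cds` are compared.
#' @return A tibble of [ks_ng86()] rows, one per pair.
#' @export
ks_pairwise <- function(cds, pairs = NULL) {
  if (is.null(pairs)) {
    ids <- sort(cds$id)
    if (length(ids) < 2) {
      return(ks_ng86("GGT", "GGT")[0, ])
    }
    cmb <- utils::combn(ids, 2)
    pairs <- tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
  }
  if (nrow(pairs) == 0) return(ks_ng86("GGT", "GGT")[0, ])
  seqs <- setNames(cds$seq, cds$id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seqs))
  if (length(missing) > 0) {
    abort(paste0("CDS missing for gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  purrr::map2(pairs$gene_a, pairs$gene_b,
              function(a, b) ks_ng86(seqs[[a]], seqs[[b]], a, b)) |>
    purrr::list_rbind()
}

#' Back-translate an aligned protein MSA to a codon MSA
#'
#' Each amino-acid column becomes the corresponding codon from the gene's
#' CDS; gaps become `---`. The ungapped protein of every row must translate
#' exactly from its CDS under the standard genetic code.
#'
#' @param protein_msa A tibble (`id`, `seq`) of aligned amino-acid sequences
#'   (gap character `-`).
#' @param cds A tibble (`id`, `seq`) of coding sequences covering all ids.
#' @return A tibble (`id`, `seq`) of aligned codon sequences.
#' @export
backtranslate <- function(protein_msa, cds) {
  seqs <- setNames(cds$seq, cds$id)
  out <- purrr::map2_chr(protein_msa$id, protein_msa$seq, function(id, aln) {
    if (!id %in% names(seqs)) abort(paste0("CDS missing for gene ", id))
    nuc <- toupper(seqs[[id]])
    aa_aln <- strsplit(aln, "")[[1]]
    aa_ungapped <- aa_aln[aa_aln != "-"]
    if (nchar(nuc) != 3 * length(aa_ungapped)) {
      abort(paste0("CDS length of ", id, " does not match its aligned protein"))
    }
    trans <- strsplit(translate_cds(nuc), "")[[1]]
    mism <- which(trans != aa_ungapped)
    if (length(mism) > 0) {
      abort(paste0("translation mismatch for gene ", id, " at position ",
                   mism[1], ": codon gives ", trans[mism[1]],
                   ", alignment has ", aa_ungapped[mism[1]]))
    }
    codons <- substring(nuc, seq(1, nchar(nuc), 3), seq(3, nchar(nuc), 3))
    k <- 0
    paste(vapply(aa_aln, function(a) {
      if (a == "-") return("---")
      k <<- k + 1
      codons[k]
    }, character(1)), collapse = "")
  })
  tibble(id = protein_msa$id, seq = out)
}

#' Average-linkage (UPGMA) family tree from a pairwise Ks matrix
#'
#' Joins the closest pair of clusters at each step; the height of an internal
#' node is the average Ks between the two clusters it joins. Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representatives (smallest member id per cluster). Saturated (`NA`) Ks
#' entries are replaced by `ks_cap`.
#'
#' @param ks Either a symmetric numeric matrix with gene ids as dimnames or a
#'   tibble with columns `gene_a`, `gene_b`, `ks`.
#' @param ks_cap Replacement value for saturated/missing Ks. Default 5.
#' @return An object of class `ksage_tree`: `leaves`, `merges` (tibble
#'   `node_id`, `height`, `size`), and `pair_nodes` mapping every leaf pair to
#'   its most recent common ancestor node and height.
#' @export
family_tree_alc <- function(ks, ks_cap = 5) {
  d <- as_ks_matrix(ks, ks_cap)
  leaves <- rownames(d)
  n <- length(leaves)
  if (n == 1) {
    return(structure(list(
      leaves = leaves,
      merges = tibble(node_id = character(), height = numeric(), size = integer()),
      pair_nodes = tibble(gene_a = character(), gene_b = character(),
                          node_id = character(), height = numeric())
    ), class = "ksage_tree"))
  }
  members <- as.list(leaves)
  reps <- leaves                 # smallest member id per active cluster
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  merges <- vector("list", n - 1)
  pair_nodes <- vector("list", n - 1)
  dm <- d
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- dm[i, j]
        cand <- sort(c(reps[i], reps[j]))
        take <- is.null(best) || dij < best_d - 1e-12
        if (!take && abs(dij - best_d) <= 1e-12) {
          take <- cand[1] < best$key[1] ||
            (cand[1] == best$key[1] && cand[2] < best$key[2])
        }
        if (take) {
          best <- list(i = min(i, j), j = max(i, j), key = cand)
          best_d <- dij
        }
      }
    }
    i <- best$i; j <- best$j
    node_id <- sprintf("N%02d", step)
    cross <- expand.grid(a = members[[i]], b = members[[j]],
                         stringsAsFactors = FALSE)
    pair_nodes[[step]] <- tibble(
      gene_a = pmin(cross$a, cross$b), gene_b = pmax(cross$a, cross$b),
      node_id = node_id, height = dm[i, j]
    )
    merges[[step]] <- tibble(node_id = node_id, height = dm[i, j],
                             size = sizes[i] + sizes[j])
    # average-linkage update into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    reps[i] <- min(reps[i], reps[j])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  structure(list(
    leaves = leaves,
    merges = purrr::list_rbind(merges),
    pair_nodes = purrr::list_rbind(pair_nodes)
  ), class = "ksage_tree")
}

as_ks_matrix <- function(ks, ks_cap) {
  if (is.matrix(ks)) {
    m <- ks
  } else {
    ids <- sort(unique(c(ks$gene_a, ks$gene_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(ks$gene_a, ks$gene_b)] <- ks$ks
    m[cbind(ks$gene_b, ks$gene_a)] <- ks$ks
  }
  if (any(m < 0, na.rm = TRUE)) abort("negative Ks in distance matrix")
  m[is.na(m)] <- ks_cap
  diag(m) <- 0
  m
}

#' Collapse redundant Ks values so each duplication event has total weight 1
#'
#' Maps every gene pair of a family to its duplication node (the most recent
#' common ancestor in the family tree) and either down-weights pairs so each
#' node's weights sum to 1 (`node_weighted`) or emits one averaged Ks per
#' node with weight 1 (`node_averaged`).
#'
#' @param tree A `ksage_tree` from [family_tree_alc()].
#' @param pair_ks A tibble with `gene_a`, `gene_b`, `ks`.
#' @param mode `"node_weighted"` or `"node_averaged"`.
#' @return A tibble `node_id`, `gene_a`, `gene_b`, `ks`, `weight` (gene ids
#'   `NA` in node-averaged mode).
#' @export
deduplicate_ks <- function(tree, pair_ks,
                           mode = c("node_weighted", "node_averaged")) {
  mode <- match.arg(mode)
  pk <- pair_ks |>
    mutate(.a = pmin(.data$gene_a, .data$gene_b),
           .b = pmax(.data$gene_a, .data$gene_b)) |>
    select(-"gene_a", -"gene_b") |>
    rename(gene_a = ".a", gene_b = ".b")
  joined <- tree$pair_nodes |>
    left_join(pk, by = c("gene_a", "gene_b"))
  if (anyNA(joined$ks)) {
    abort("pair_ks does not cover every leaf pair of the tree")
  }
  if (mode == "node_weighted") {
    joined |>
      group_by(.data$node_id) |>
      mutate(weight = 1 / dplyr::n()) |>
      ungroup() |>
      select("node_id", "gene_a", "gene_b", "ks", "weight")
  } else {
    joined |>
      group_by(.data$node_id) |>
      summarise(ks = mean(.data$ks), .groups = "drop") |>
      mutate(gene_a = NA_character_, gene_b = NA_character_, weight = 1) |>
      select("node_id", "gene_a", "gene_b", "ks", "weight")
  }
}

#' Build a weighted Ks age distribution for a set of gene families
#'
#' For each family: all pairwise NG86 Ks estimates, an average-linkage family
#' tree, and node-weighted or node-averaged redundancy removal, so each
#' duplication event contributes total weight 1.
#'
#' @param families A tibble `family_id`, `gene_id`.
#' @param cds A tibble (`id`, `seq`) of coding sequences.
#' @param mode Redundancy-removal mode, see [deduplicate_ks()].
#' @param ks_cap Cap for saturated Ks when building trees. Default 5.
#' @return A tibble `family_id`, `node_id`, `gene_a`, `gene_b`, `ks`,
#'   `weight`, `saturated`. Saturated pairs enter at the cap value and are
#'   flagged so downstream fitting can exclude them.
#' @export
ks_distribution <- function(families, cds,
                            mode = c("node_weighted", "node_averaged"),
                            ks_cap = 5) {
  mode <- match.arg(mode)
  fams <- split(families$gene_id, families$family_id)
  fams <- fams[lengths(fams) >= 2]
  out <- imap(fams, function(genes, fid) {
    est <- ks_pairwise(cds[cds$id %in% genes, , drop = FALSE])
    pk <- est |>
      transmute(.data$gene_a, .data$gene_b,
                ks = ifelse(.data$saturated_ks, ks_cap, .data$ks),
                saturated = .data$saturated_ks)
    tree <- family_tree_alc(pk[, c("gene_a", "gene_b", "ks")], ks_cap = ks_cap)
    dd <- deduplicate_ks(tree, pk[, c("gene_a", "gene_b", "ks")], mode = mode)
    if (mode == "node_weighted") {
      dd <- dd |> left_join(pk[, c("gene_a", "gene_b", "saturated")],
                            by = c("gene_a", "gene_b"))
    } else {
      sat_nodes <- tree$pair_nodes |>
        left_join(pk[, c("gene_a", "gene_b", "saturated")],
                  by = c("gene_a", "gene_b")) |>
        group_by(.data$node_id) |>
        summarise(saturated = any(.data$saturated), .groups = "drop")
      dd <- dd |> left_join(sat_nodes, by = "node_id")
    }
    dd$family_id <- fid
    dd
  })
  purrr::list_rbind(out) |>
    select("family_id", "node_id", "gene_a", "gene_b", "ks", "weight",
           "saturated")
}

#' Ks values for orthologous gene pairs
#'
#' One NG86 Ks per reciprocal-best-hit pair; no tree weighting is needed
#' because each pair reflects a single speciation event. Saturated pairs are
#' excluded, with the count reported as a message and in the
#' `n_saturated` attribute.
#'
#' @param cds_a,cds_b Tibbles (`id`, `seq`) of coding sequences for the two
#'   species.
#' @param pairs A tibble `gene_a` (species A), `gene_b` (species B).
#' @return A tibble `gene_a`, `gene_b`, `ks`.
#' @export
ortholog_ks <- function(cds_a, cds_b, pairs) {
  if (nrow(pairs) == 0) {
    out <- tibble(gene_a = character(), gene_b = character(), ks = numeric())
    attr(out, "n_saturated") <- 0L
    return(out)
  }
  cds <- bind_rows(cds_a, cds_b) |> distinct(.data$id, .keep_all = TRUE)
  est <- ks_pairwise(cds, pairs)
  n_sat <- sum(est$saturated_ks)
  if (n_sat > 0) inform(paste0(n_sat, " saturated ortholog pair(s) excluded"))
  out <- est |>
    filter(!.data$saturated_ks) |>
    select("gene_a", "gene_b", "ks")
  attr(out, "n_saturated") <- n_sat
  out
}

#' Three-point decomposition of trio Ks modes into branch contributions
#'
#' Given the Ks-distribution modes of the three ortholog comparisons of a
#' (focal, sister, outgroup) trio, recovers the lineage-specific branch
#' lengths from the focal/sister split by the closed form
#' `b_focal = (m_fs + m_fo - m_so)/2`, `b_sister = (m_fs + m_so - m_fo)/2`.
#'
#' @param mode_fo,mode_so,mode_fs Ks modes of the (focal, outgroup),
#'   (sister, outgroup) and (focal, sister) distributions.
#' @return A one-row tibble `b_focal`, `b_sister`. Negative estimates are
#'   returned as-is with a warning.
#' @export
trio_branch_ks <- function(mode_fo, mode_so, mode_fs) {
  b_focal <- (mode_fs + mode_fo - mode_so) / 2
  b_sister <- (mode_fs + mode_so - mode_fo) / 2
  if (b_focal < 0 || b_sister < 0) {
    warn("negative branch Ks estimate in trio decomposition")
  }
  tibble(b_focal = b_focal, b_sister = b_sister)
}
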