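# Codon-level machinery shared by the NG86 Ks estimator and the synthetic
# sequence evolver. All tables are computed once per session and cached.
#
# Site-counting convention: per codon position, the fraction of the three
# possible single-nucleotide changes that are synonymous contributes to the
# synonymous site count; changes creating stop codons count as nonsynonymous
# sites, so S + N == 3 per compared codon. Substitution *paths* that pass
# through a stop codon are excluded from difference counting (all-paths
# fallback when every ordering is blocked).

codon_tables <- function() {
  if (!is.null(the$codon_tables)) return(the$codon_tables)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  nt <- c("A", "C", "G", "T")
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)

  mutate1 <- function(codon, pos, base) {
    substr(codon, pos, pos) <- base
    codon
  }

  # per-codon synonymous site count (stops get NA; never compared)
  syn_sites <- rep(NA_real_, n)
  syn_neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    s <- 0
    nb <- character(0)
    for (p in 1:3) {
      cur <- substr(codons[i], p, p)
      for (b in setdiff(nt, cur)) {
        alt <- mutate1(codons[i], p, b)
        if (aa[idx[alt]] == aa[i]) {
          s <- s + 1 / 3
          nb <- c(nb, alt)
        }
      }
    }
    syn_sites[i] <- s
    syn_neighbors[[i]] <- nb
  }

  # pairwise expected synonymous / nonsynonymous differences, averaged over
  # all orderings of the differing positions
  sd_mat <- matrix(NA_real_, n, n)
  nd_mat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    sd_mat[i, i] <- 0
    nd_mat[i, i] <- 0
    for (j in seq_len(n)) {
      if (j <= i || aa[j] == "*") next
      pos <- which(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      perms <- permutations_of(pos)
      sd_tot <- nd_tot <- 0
      sd_all <- nd_all <- 0
      n_valid <- 0
      for (ord in perms) {
        cur <- codons[i]
        s <- ns <- 0
        blocked <- FALSE
        for (p in ord) {
          nxt <- mutate1(cur, p, substr(codons[j], p, p))
          if (aa[idx[nxt]] == "*") blocked <- TRUE
          if (aa[idx[nxt]] == aa[idx[cur]]) s <- s + 1 else ns <- ns + 1
          cur <- nxt
        }
        sd_all <- sd_all + s
        nd_all <- nd_all + ns
        if (!blocked) {
          sd_tot <- sd_tot + s
          nd_tot <- nd_tot + ns
          n_valid <- n_valid + 1
        }
      }
      if (n_valid > 0) {
        sd_mat[i, j] <- sd_tot / n_valid
        nd_mat[i, j] <- nd_tot / n_valid
      } else {
        sd_mat[i, j] <- sd_all / length(perms)
        nd_mat[i, j] <- nd_all / length(perms)
      }
      sd_mat[j, i] <- sd_mat[i, j]
      nd_mat[j, i] <- nd_mat[i, j]
    }
  }

  the$codon_tables <- list(
    codons = codons, aa = aa, idx = idx,
    syn_sites = syn_sites, syn_neighbors = syn_neighbors,
    sd_mat = sd_mat, nd_mat = nd_mat,
    non_stop = codons[aa != "*"]
  )
  the$codon_tables
}

# all orderings of a position vector (length <= 3, so at most 6)
permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in permutations_of(x[-k])) out[[length(out) + 1]] <- c(x[k], rest)
  }
  out
}

# split a CDS string into codon index vector; non-ACGT or stop codons -> NA
codon_indices <- function(seq) {
  tab <- codon_tables()
  if (nchar(seq) %% 3 != 0) {
    abort("CDS length not divisible by 3")
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  i <- unname(tab$idx[codons])
  i[!is.na(i) & tab$aa[i] == "*"] <- NA_integer_
  i
}

#' Translate a CDS to protein (standard genetic code)
#'
#' @param seq A coding nucleotide sequence (length divisible by 3).
#' @return The amino-acid string; stop codons become `*`.
#' @export
translate_cds <- function(seq) {
  tab <- codon_tables()
  codons <- substring(toupper(seq), seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  i <- tab$idx[codons]
  paste(ifelse(is.na(i), "X", tab$aa[i]), collapse = "")
}
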