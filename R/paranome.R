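#' Correct gene-length bias in similarity bit-scores
#'
#' Longer genes get larger bit-scores regardless of similarity. Hits are
#' sorted by proxy gene length (product of query and target amino-acid
#' lengths) and split into `n_bins` equal-count bins; within each bin the top
#' `top_percent` of hits by bit-score are selected, and an ordinary
#' least-squares regression of `log10(bitscore)` on `log10(proxy_len)` is
#' fitted to the selected hits. Each hit's bit-score is then normalized by
#' the regression-expected bit-score at its proxy length.
#'
#' @param hits A hits tibble (see [read_hits()]) with `bitscore` and
#'   `proxy_len`.
#' @param n_bins Number of equal-count bins. Default 100.
#' @param top_percent Percentage of top hits per bin entering the regression
#'   (at least one hit per bin). Default 5.
#' @return A list with `hits` (input with `norm_score` filled) and `fit`, a
#'   `ksage_norm_fit` holding `slope`, `intercept`, `r_squared_upper` and the
#'   before/after all-hit R-squared values.
#' @export
normalize_bitscores <- function(hits, n_bins = 100, top_percent = 5) {
  n <- nrow(hits)
  if (n < 1) abort("no hits to normalize")
  stopifnot(top_percent > 0, top_percent <= 100)
  r2 <- function(x, y) {
    if (length(unique(x)) < 2) return(NA_real_)
    summary(lm(y ~ x))$r.squared
  }
  lx_all <- log10(hits$proxy_len)
  r2_before <- r2(lx_all, log10(hits$bitscore))
  if (length(unique(hits$proxy_len)) < 2) {
    warn("all hits share one proxy length; normalizing by geometric mean bit-score")
    gm <- exp(mean(log(hits$bitscore)))
    hits$norm_score <- hits$bitscore / gm
    fit <- structure(list(
      n_bins = n_bins, top_percent = top_percent, slope = 0,
      intercept = log10(gm), r_squared_upper = NA_real_,
      r_squared_all_before = r2_before, r_squared_all_after = NA_real_,
      n_hits = n, n_selected = n, degenerate = TRUE
    ), class = "ksage_norm_fit")
    return(list(hits = hits, fit = fit))
  }
  if (n_bins > n) {
    warn(paste0("n_bins (", n_bins, ") exceeds hit count (", n, "); clamped"))
    n_bins <- n
  }
  ord <- order(hits$proxy_len, hits$bitscore)
  base <- n %/% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= n %% n_bins)
  bin <- rep.int(seq_len(n_bins), sizes)
  sel_rows <- unlist(lapply(split(ord, bin), function(rows) {
    m <- max(1L, ceiling(top_percent / 100 * length(rows)))
    rows[order(hits$bitscore[rows], decreasing = TRUE)[seq_len(m)]]
  }), use.names = FALSE)
  lx <- log10(hits$proxy_len[sel_rows])
  ly <- log10(hits$bitscore[sel_rows])
  reg <- lm(ly ~ lx)
  slope <- unname(coef(reg)[2])
  intercept <- unname(coef(reg)[1])
  expected <- 10^(intercept + slope * lx_all)
  hits$norm_score <- hits$bitscore / expected
  fit <- structure(list(
    n_bins = n_bins, top_percent = top_percent,
    slope = slope, intercept = intercept,
    r_squared_upper = summary(reg)$r.squared,
    r_squared_all_before = r2_before,
    r_squared_all_after = r2(lx_all, log10(hits$norm_score)),
    n_hits = n, n_selected = length(sel_rows), degenerate = FALSE
  ), class = "ksage_norm_fit")
  list(hits = hits, fit = fit)
}

#' @export
print.ksage_norm_fit <- function(x, ...) {
  cat("Bit-score normalization fit\n")
  cat(sprintf("  bins: %d, top %% per bin: %g (selected %d of %d hits)\n",
              x$n_bins, x$top_percent, x$n_selected, x$n_hits))
  cat(sprintf("  log10(bitscore) = %.4f + %.4f * log10(proxy_len)  (R2 upper = %.3f)\n",
              x$intercept, x$slope, x$r_squared_upper))
  cat(sprintf("  all-hit R2 vs length: before = %.4f, after = %.4f\n",
              x$r_squared_all_before, x$r_squared_all_after))
  invisible(x)
}

#' Markov clustering of a weighted gene-similarity graph
#'
#' Builds a column-stochastic transition matrix from the symmetrized edge
#' weights with self-loops set to each node's maximum incident weight, then
#' alternates expansion (matrix squaring) and inflation (entrywise power and
#' column renormalization) until convergence. Clusters are read off as the
#' connected components of the converged matrix's nonzero structure, so every
#' input gene belongs to exactly one family.
#'
#' @param edges A tibble with columns `gene_a`, `gene_b`, `weight`
#'   (non-negative; typically normalized bit-scores). Multiple rows per pair
#'   keep the maximum weight.
#' @param inflation Inflation exponent (> 1). Default 2.
#' @param max_iter Maximum iterations. Default 100.
#' @param tol Convergence tolerance on the maximum entry change. Default 1e-6.
#' @param prune Entries below this are zeroed each iteration. Default 1e-8.
#' @param nodes Optional character vector of gene ids to include even if
#'   isolated (they become singleton families).
#' @return A tibble `family_id`, `gene_id`, `is_singleton`; families are
#'   numbered by decreasing size, ties by smallest member id.
#' @export
markov_cluster <- function(edges, inflation = 2, max_iter = 100, tol = 1e-6,
                           prune = 1e-8, nodes = NULL) {
  stopifnot(inflation > 1)
  if (nrow(edges) > 0 && any(edges$weight < 0)) {
    abort("negative edge weight in markov_cluster")
  }
  genes <- sort(unique(c(edges$gene_a, edges$gene_b, nodes)))
  if (length(genes) == 0) {
    return(tibble(family_id = character(), gene_id = character(),
                  is_singleton = logical()))
  }
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(edges) > 0) {
    e <- edges |>
      mutate(.a = pmin(.data$gene_a, .data$gene_b),
             .b = pmax(.data$gene_a, .data$gene_b)) |>
      group_by(.data$.a, .data$.b) |>
      summarise(weight = max(.data$weight), .groups = "drop") |>
      filter(.data$.a != .data$.b)
    A[cbind(e$.a, e$.b)] <- e$weight
    A[cbind(e$.b, e$.a)] <- e$weight
  }
  loop <- apply(A, 2, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # clusters = connected components of the nonzero structure
  adj <- (M > 0) | (t(M) > 0)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  fam <- tibble(gene_id = genes, comp = comp) |>
    group_by(.data$comp) |>
    mutate(size = dplyr::n(), min_id = min(.data$gene_id)) |>
    ungroup() |>
    arrange(desc(.data$size), .data$min_id, .data$gene_id)
  ids <- fam |> distinct(.data$comp) |> mutate(family_id = sprintf("GF%06d", dplyr::row_number()))
  fam |>
    left_join(ids, by = "comp") |>
    mutate(is_singleton = .data$size == 1L) |>
    select("family_id", "gene_id", "is_singleton")
}

#' Reciprocal best hits between two species
#'
#' A pair `(a, b)` is returned iff `b` is `a`'s highest-scoring hit in the
#' other species and vice versa. Ties are broken by lower e-value, then by
#' lexicographic target id.
#'
#' @param hits A hits tibble with `query`, `target`, `bitscore`, `evalue`.
#' @param species Named character vector mapping gene id to species label.
#' @param score_col Column used as the score. Default `"bitscore"`.
#' @return A tibble `gene_a`, `gene_b`, `species_a`, `species_b` with
#'   `species_a < species_b`; one row per RBH pair, all species pairs present
#'   in the hits are processed.
#' @export
reciprocal_best_hits <- function(hits, species, score_col = "bitscore") {
  if (nrow(hits) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  species_a = character(), species_b = character()))
  }
  if (is.data.frame(species)) species <- setNames(species$species, species$id)
  # symmetric directional view
  long <- bind_rows(
    tibble(from = hits$query, to = hits$target,
           score = hits[[score_col]], evalue = hits$evalue),
    tibble(from = hits$target, to = hits$query,
           score = hits[[score_col]], evalue = hits$evalue)
  ) |>
    distinct() |>
    mutate(sp_from = unname(species[.data$from]),
           sp_to = unname(species[.data$to])) |>
    filter(.data$sp_from != .data$sp_to)
  if (nrow(long) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  species_a = character(), species_b = character()))
  }
  best <- long |>
    arrange(.data$from, .data$sp_to, desc(.data$score), .data$evalue,
            .data$to) |>
    distinct(.data$from, .data$sp_to, .keep_all = TRUE)
  key <- paste(best$from, best$to)
  rev_key <- paste(best$to, best$from)
  mutual <- best[key %in% rev_key, ]
  mutual |>
    mutate(
      gene_a = ifelse(.data$sp_from < .data$sp_to, .data$from, .data$to),
      gene_b = ifelse(.data$sp_from < .data$sp_to, .data$to, .data$from),
      species_a = pmin(.data$sp_from, .data$sp_to),
      species_b = pmax(.data$sp_from, .data$sp_to)
    ) |>
    distinct(.data$gene_a, .data$gene_b, .data$species_a, .data$species_b) |>
    arrange(.data$species_a, .data$species_b, .data$gene_a, .data$gene_b)
}

#' Assemble orthogroups around anchor pairs for absolute WGD dating
#'
#' One orthogroup per retained anchor pair: the two focal-species paralogs
#' plus, for each other species, the reciprocal-best-hit partner(s) of either
#' paralog. Groups missing more than `max_missing` of the other species are
#' dropped (default: all species required).
#'
#' @param anchor_pairs Tibble `gene_a`, `gene_b` of focal-species anchor
#'   pairs.
#' @param rbh_sets Named list (species label -> tibble with columns `focal`,
#'   `other`) of RBH pairs between the focal species and each other species.
#' @param max_missing Number of other species allowed to be absent. Default 0.
#' @return A tibble `orthogroup_id`, `gene_id`, `species`, `role` (`"focal"`
#'   or `"ortholog"`); empty if nothing passes.
#' @export
assemble_dating_orthogroups <- function(anchor_pairs, rbh_sets,
                                        max_missing = 0) {
  out <- list()
  og <- 0L
  for (i in seq_len(nrow(anchor_pairs))) {
    p1 <- anchor_pairs$gene_a[i]; p2 <- anchor_pairs$gene_b[i]
    members <- tibble(gene_id = c(p1, p2), species = "focal", role = "focal")
    missing <- 0L
    for (sp in names(rbh_sets)) {
      partners <- rbh_sets[[sp]] |>
        filter(.data$focal %in% c(p1, p2)) |>
        pull("other") |>
        unique() |>
        sort()
      if (length(partners) == 0) {
        missing <- missing + 1L
      } else {
        members <- bind_rows(members, tibble(gene_id = partners, species = sp,
                                             role = "ortholog"))
      }
    }
    if (missing > max_missing) next
    og <- og + 1L
    members$orthogroup_id <- sprintf("OG%04d", og)
    out[[og]] <- members
  }
  if (length(out) == 0) {
    return(tibble(orthogroup_id = character(), gene_id = character(),
                  species = character(), role = character()))
  }
  purrr::list_rbind(out) |>
    select("orthogroup_id", "gene_id", "species", "role")
}
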