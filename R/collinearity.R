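#' Detect collinear segments by gap-bounded diagonal chaining
#'
#' Homolog pairs are mapped into per-chromosome gene-rank space and chained
#' greedily along diagonals: within a chromosome pair, matches sorted by rank
#' extend a chain when both rank increments are in `[1, max_gap]` (both
#' orientations are tried, so inverted blocks are found as descending
#' chains). Chains with at least `min_genes` anchors whose base-pair span on
#' both regions reaches `min_length_bp` are kept; chains whose anchor sets
#' overlap by at least half are considered redundant and only the
#' anchor-richest is retained. Tandem arrays (consecutive homologs of one
#' gene within `max_gap` ranks) are collapsed to one representative before
#' chaining.
#'
#' @param loci_a Gene loci tibble (see [read_gff_genes()]) for the first
#'   genome.
#' @param homolog_pairs Tibble `gene_a`, `gene_b` (optionally `score`).
#' @param loci_b Loci for the second genome; `NULL` (default) for an
#'   intra-genome search.
#' @param max_gap Maximum rank gap between consecutive anchors. Default 25.
#' @param min_genes Minimum anchors per segment. Default 3.
#' @param min_length_bp Minimum base-pair span of both regions.
#'   Default 100000.
#' @param redundancy_overlap Anchor-set overlap fraction above which two
#'   chains are redundant. Default 0.5.
#' @return A tibble with one row per segment: region rank/bp bounds for both
#'   sides, `n_anchors`, `span_bp_a`, `span_bp_b`, `orientation`, `intra`,
#'   and an `anchors` list-column (`gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
detect_segments <- function(loci_a, homolog_pairs, loci_b = NULL,
                            max_gap = 25, min_genes = 3,
                            min_length_bp = 100000,
                            redundancy_overlap = 0.5) {
  intra <- is.null(loci_b)
  if (intra) loci_b <- loci_a
  empty <- tibble(
    segment_id = character(), chrom_a = character(),
    start_rank_a = integer(), end_rank_a = integer(),
    chrom_b = character(), start_rank_b = integer(), end_rank_b = integer(),
    start_bp_a = integer(), end_bp_a = integer(),
    start_bp_b = integer(), end_bp_b = integer(),
    n_anchors = integer(), span_bp_a = integer(), span_bp_b = integer(),
    orientation = integer(), intra = logical(), anchors = list()
  )
  if (nrow(homolog_pairs) == 0) return(empty)
  la <- loci_a |> select(gene_a = "gene_id", chrom_a = "chromosome",
                         rank_a = "rank", start_a = "start", end_a = "end")
  lb <- loci_b |> select(gene_b = "gene_id", chrom_b = "chromosome",
                         rank_b = "rank", start_b = "start", end_b = "end")
  if (!"score" %in% names(homolog_pairs)) homolog_pairs$score <- 0
  m <- homolog_pairs |>
    filter(.data$gene_a != .data$gene_b) |>
    inner_join(la, by = "gene_a") |>
    inner_join(lb, by = "gene_b")
  if (intra) {
    # canonical orientation of each match, then drop mirrored duplicates
    flip <- m$chrom_b < m$chrom_a |
      (m$chrom_a == m$chrom_b & m$rank_b < m$rank_a)
    m[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b",
              "start_a", "start_b", "end_a", "end_b")] <-
      m[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a",
                "start_b", "start_a", "end_b", "end_a")]
    m <- distinct(m, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  }
  if (nrow(m) == 0) return(empty)
  m <- collapse_tandems(m, max_gap)
  chains <- list()
  for (grp in split(m, paste(m$chrom_a, m$chrom_b))) {
    for (orient in c(1L, -1L)) {
      g <- grp |>
        mutate(rb = orient * .data$rank_b) |>
        arrange(.data$rank_a, .data$rb)
      open <- list()   # each: list(last_a, last_b, rows)
      for (r in seq_len(nrow(g))) {
        placed <- FALSE
        if (length(open) > 0) {
          for (ci in rev(seq_along(open))) {
            da <- g$rank_a[r] - open[[ci]]$last_a
            db <- g$rb[r] - open[[ci]]$last_b
            if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap) {
              open[[ci]]$rows <- c(open[[ci]]$rows, r)
              open[[ci]]$last_a <- g$rank_a[r]
              open[[ci]]$last_b <- g$rb[r]
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          open[[length(open) + 1]] <- list(last_a = g$rank_a[r],
                                           last_b = g$rb[r], rows = r)
        }
      }
      for (ch in open) {
        if (length(ch$rows) < min_genes) next
        chains[[length(chains) + 1]] <-
          list(anchors = g[ch$rows, ], orientation = orient)
      }
    }
  }
  if (length(chains) == 0) return(empty)
  segs <- purrr::imap(chains, function(ch, i) {
    a <- ch$anchors
    tibble(
      chrom_a = a$chrom_a[1],
      start_rank_a = min(a$rank_a), end_rank_a = max(a$rank_a),
      chrom_b = a$chrom_b[1],
      start_rank_b = min(a$rank_b), end_rank_b = max(a$rank_b),
      start_bp_a = min(a$start_a), end_bp_a = max(a$end_a),
      start_bp_b = min(a$start_b), end_bp_b = max(a$end_b),
      n_anchors = nrow(a),
      span_bp_a = max(a$end_a) - min(a$start_a),
      span_bp_b = max(a$end_b) - min(a$start_b),
      orientation = ch$orientation,
      intra = intra,
      anchors = list(a |> select("gene_a", "gene_b", "rank_a", "rank_b"))
    )
  }) |> purrr::list_rbind()
  segs <- segs |>
    filter(.data$n_anchors >= min_genes,
           .data$span_bp_a >= min_length_bp,
           .data$span_bp_b >= min_length_bp)
  if (nrow(segs) == 0) return(empty)
  # redundancy removal: keep anchor-richest among chains sharing >= half of
  # their anchor pairs
  segs <- segs |> arrange(desc(.data$n_anchors), .data$chrom_a,
                          .data$start_rank_a, .data$chrom_b,
                          .data$start_rank_b)
  keys <- purrr::map(segs$anchors, function(a) paste(a$gene_a, a$gene_b))
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(segs))) {
      if (j <= i || !keep[j]) next
      ov <- length(intersect(keys[[i]], keys[[j]])) /
        min(length(keys[[i]]), length(keys[[j]]))
      if (ov >= redundancy_overlap) keep[j] <- FALSE
    }
  }
  segs <- segs[keep, ]
  segs |>
    mutate(segment_id = sprintf("SEG%04d", dplyr::row_number())) |>
    select("segment_id", dplyr::everything())
}

# collapse tandem arrays: runs of matches sharing one side and lying within
# max_gap ranks on the other are represented by the best-scoring match
collapse_tandems <- function(m, max_gap) {
  collapse_side <- function(m, fixed, run_rank) {
    m <- m |> arrange(.data$chrom_a, .data$chrom_b, .data[[fixed]],
                      .data[[run_rank]])
    grp <- paste(m$chrom_a, m$chrom_b, m[[fixed]])
    new_run <- c(TRUE, grp[-1] != grp[-length(grp)] |
                   diff(m[[run_rank]]) > max_gap)
    m$run <- cumsum(new_run)
    m |>
      group_by(.data$run) |>
      arrange(desc(.data$score), .data[[run_rank]], .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      select(-"run")
  }
  m |>
    collapse_side("rank_a", "rank_b") |>
    collapse_side("rank_b", "rank_a")
}

#' Stack segment intervals along chromosomes (dupstack table)
#'
#' Projects every segment onto the chromosomes it touches and assigns
#' non-overlapping display lanes, longest interval first.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @return A tibble `chromosome`, `segment_id`, `side`, `start_bp`, `end_bp`,
#'   `scope` (`"intra"`/`"inter"`), `lane`.
#' @export
dupstack <- function(segments) {
  if (nrow(segments) == 0) {
    return(tibble(chromosome = character(), segment_id = character(),
                  side = character(), start_bp = integer(),
                  end_bp = integer(), scope = character(), lane = integer()))
  }
  iv <- bind_rows(
    segments |> transmute(chromosome = .data$chrom_a,
                          segment_id = .data$segment_id, side = "a",
                          start_bp = .data$start_bp_a, end_bp = .data$end_bp_a,
                          scope = ifelse(.data$intra, "intra", "inter")),
    segments |> transmute(chromosome = .data$chrom_b,
                          segment_id = .data$segment_id, side = "b",
                          start_bp = .data$start_bp_b, end_bp = .data$end_bp_b,
                          scope = ifelse(.data$intra, "intra", "inter"))
  )
  iv |>
    group_by(.data$chromosome) |>
    group_modify(function(d, key) {
      d <- d |> arrange(desc(.data$end_bp - .data$start_bp),
                        .data$start_bp, .data$segment_id, .data$side)
      lane_ends <- numeric(0)
      d$lane <- NA_integer_
      for (i in seq_len(nrow(d))) {
        placed <- which(lane_ends <= d$start_bp[i])
        if (length(placed) > 0) {
          l <- placed[1]
        } else {
          lane_ends <- c(lane_ends, -Inf)
          l <- length(lane_ends)
        }
        lane_ends[l] <- d$end_bp[i]
        d$lane[i] <- l
      }
      d
    }) |>
    ungroup()
}

#' Multiplication-level profile of collinear segments (syndepth)
#'
#' Segment regions overlapping by at least `overlap` of the shorter region's
#' rank span are merged; each homeologous group (connected component over
#' merged regions linked by segments) gets a multiplication level equal to
#' its number of distinct regions. Intra- and inter-genome segments are
#' profiled separately.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @param overlap Rank-overlap fraction that merges two regions. Default 0.5.
#' @return A tibble `scope`, `level`, `n_groups`.
#' @export
syndepth <- function(segments, overlap = 0.5) {
  if (nrow(segments) == 0) {
    return(tibble(scope = character(), level = integer(), n_groups = integer()))
  }
  profile_one <- function(segs, scope) {
    regions <- bind_rows(
      segs |> transmute(chrom = .data$chrom_a, lo = .data$start_rank_a,
                        hi = .data$end_rank_a, seg = .data$segment_id),
      segs |> transmute(chrom = .data$chrom_b, lo = .data$start_rank_b,
                        hi = .data$end_rank_b, seg = .data$segment_id)
    )
    nr <- nrow(regions)
    parent <- seq_len(nr)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    # 1) merge overlapping regions into region classes
    for (i in seq_len(nr)) {
      for (j in seq_len(i - 1L)) {
        if (regions$chrom[i] != regions$chrom[j]) next
        ov <- min(regions$hi[i], regions$hi[j]) -
          max(regions$lo[i], regions$lo[j]) + 1
        shorter <- min(regions$hi[i] - regions$lo[i],
                       regions$hi[j] - regions$lo[j]) + 1
        if (ov / shorter >= overlap) union_(i, j)
      }
    }
    region_class <- vapply(seq_len(nr), find, integer(1))
    # 2) connect the two regions of each segment, over classes
    classes <- unique(region_class)
    cparent <- setNames(classes, classes)
    cfind <- function(i) {
      while (cparent[[as.character(i)]] != i) i <- cparent[[as.character(i)]]
      i
    }
    for (s in seq_len(nrow(segs))) {
      c1 <- cfind(region_class[s])
      c2 <- cfind(region_class[s + nrow(segs)])
      if (c1 != c2) cparent[[as.character(max(c1, c2))]] <- min(c1, c2)
    }
    groups <- vapply(classes, cfind, numeric(1))
    tibble(class = classes, group = groups) |>
      count(.data$group, name = "level") |>
      count(.data$level, name = "n_groups") |>
      mutate(scope = scope)
  }
  bind_rows(
    if (any(segments$intra)) profile_one(filter(segments, .data$intra), "intra"),
    if (any(!segments$intra)) profile_one(filter(segments, !.data$intra), "inter")
  ) |>
    select("scope", "level", "n_groups") |>
    arrange(.data$scope, .data$level)
}

#' Gene homology dot-plot table
#'
#' Assigns each gene a cumulative index over chromosomes ordered by
#' decreasing length (then name) and emits one dot per homolog pair, flagged
#' as anchor when the pair lies in a collinear segment, with its Ks when
#' available.
#'
#' @param loci_a,loci_b Gene loci tibbles (use the same for an intra-genome
#'   plot).
#' @param homolog_pairs Tibble `gene_a`, `gene_b`.
#' @param anchor_set Optional tibble `gene_a`, `gene_b` of anchor pairs (as
#'   from [segment_anchors()]).
#' @param ks_lookup Optional tibble `gene_a`, `gene_b`, `ks`.
#' @return A tibble `gene_a`, `gene_b`, `x`, `y`, `is_anchor`, `ks`.
#' @export
dotplot_table <- function(loci_a, loci_b, homolog_pairs, anchor_set = NULL,
                          ks_lookup = NULL) {
  cum_index <- function(loci) {
    ord <- loci |>
      group_by(.data$chromosome) |>
      summarise(len = max(.data$end), n = dplyr::n(), .groups = "drop") |>
      arrange(desc(.data$len), .data$chromosome) |>
      mutate(offset = cumsum(dplyr::lag(.data$n, default = 0L)))
    loci |>
      left_join(ord[, c("chromosome", "offset")], by = "chromosome") |>
      transmute(gene_id = .data$gene_id,
                index = .data$offset + .data$rank)
  }
  ia <- cum_index(loci_a); ib <- cum_index(loci_b)
  canon <- function(p) {
    tibble(.a = pmin(p$gene_a, p$gene_b), .b = pmax(p$gene_a, p$gene_b))
  }
  out <- homolog_pairs |>
    left_join(ia |> rename(gene_a = "gene_id", x = "index"), by = "gene_a") |>
    left_join(ib |> rename(gene_b = "gene_id", y = "index"), by = "gene_b") |>
    select("gene_a", "gene_b", "x", "y")
  anchor_keys <- if (!is.null(anchor_set) && nrow(anchor_set) > 0) {
    k <- canon(anchor_set); paste(k$.a, k$.b)
  } else character(0)
  pk <- canon(out)
  out$is_anchor <- paste(pk$.a, pk$.b) %in% anchor_keys
  if (!is.null(ks_lookup) && nrow(ks_lookup) > 0) {
    kk <- canon(ks_lookup)
    ks_map <- setNames(ks_lookup$ks, paste(kk$.a, kk$.b))
    out$ks <- unname(ks_map[paste(pk$.a, pk$.b)])
  } else {
    out$ks <- NA_real_
  }
  out
}

#' Extract the anchor pairs of a segment table
#'
#' @param segments Segment tibble from [detect_segments()].
#' @return A tibble `gene_a`, `gene_b`, `segment_id` (unique unordered
#'   pairs; a pair appearing in several segments keeps the first).
#' @export
segment_anchors <- function(segments) {
  if (nrow(segments) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  segment_id = character()))
  }
  segments |>
    select("segment_id", "anchors") |>
    tidyr::unnest("anchors") |>
    mutate(.a = pmin(.data$gene_a, .data$gene_b),
           .b = pmax(.data$gene_a, .data$gene_b)) |>
    distinct(.data$.a, .data$.b, .keep_all = TRUE) |>
    transmute(gene_a = .data$.a, gene_b = .data$.b,
              segment_id = .data$segment_id)
}

#' Weighted Ks distribution restricted to anchor pairs
#'
#' Groups anchor pairs into anchor families (connected components of the
#' anchor-pair graph), computes or looks up NG86 Ks per pair, and applies the
#' same node-weighted / node-averaged redundancy removal as the whole-paranome
#' distribution.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @param ks_estimates Optional tibble `gene_a`, `gene_b`, `ks` of
#'   precomputed estimates; pairs not covered are computed from `cds`.
#' @param cds Optional CDS tibble (`id`, `seq`) for on-demand estimation.
#' @param mode Redundancy-removal mode. Default `"node_weighted"`.
#' @param ks_cap Saturation cap for tree building. Default 5.
#' @return A tibble `family_id`, `node_id`, `gene_a`, `gene_b`, `ks`,
#'   `weight`, `saturated`; anchors without Ks or CDS are skipped with a
#'   message.
#' @export
anchor_ks <- function(segments, ks_estimates = NULL, cds = NULL,
                      mode = c("node_weighted", "node_averaged"), ks_cap = 5) {
  mode <- match.arg(mode)
  empty <- tibble(family_id = character(), node_id = character(),
                  gene_a = character(), gene_b = character(),
                  ks = numeric(), weight = numeric(), saturated = logical())
  anchors <- segment_anchors(segments)
  if (nrow(anchors) == 0) return(empty)
  # families = connected components of the anchor-pair graph
  genes <- sort(unique(c(anchors$gene_a, anchors$gene_b)))
  parent <- seq_along(genes)
  findi <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(anchors))) {
    i <- findi(match(anchors$gene_a[r], genes))
    j <- findi(match(anchors$gene_b[r], genes))
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  root <- vapply(seq_along(genes), findi, integer(1))
  fam <- tibble(gene_id = genes,
                family_id = sprintf("ANC%04d", match(root, sort(unique(root)))))
  if (is.null(ks_estimates)) {
    ks_estimates <- tibble(gene_a = character(), gene_b = character(),
                           ks = numeric())
  }
  ke <- ks_estimates |>
    mutate(.a = pmin(.data$gene_a, .data$gene_b),
           .b = pmax(.data$gene_a, .data$gene_b))
  have <- paste(ke$.a, ke$.b)
  need <- anchors |> filter(!paste(.data$gene_a, .data$gene_b) %in% have)
  if (nrow(need) > 0) {
    if (is.null(cds)) {
      inform(paste0(nrow(need), " anchor pair(s) without Ks skipped"))
    } else {
      computable <- need |>
        filter(.data$gene_a %in% cds$id & .data$gene_b %in% cds$id)
      n_skip <- nrow(need) - nrow(computable)
      if (n_skip > 0) inform(paste0(n_skip, " anchor pair(s) without CDS skipped"))
      if (nrow(computable) > 0) {
        est <- ks_pairwise(cds, computable[, c("gene_a", "gene_b")]) |>
          mutate(ks = ifelse(.data$saturated_ks, NA_real_, .data$ks))
        ke <- bind_rows(ke, est |>
                          mutate(.a = pmin(.data$gene_a, .data$gene_b),
                                 .b = pmax(.data$gene_a, .data$gene_b)) |>
                          select(".a", ".b", "ks", gene_a = "gene_a",
                                 gene_b = "gene_b"))
      }
    }
  }
  ks_map <- setNames(ke$ks, paste(ke$.a, ke$.b))
  out <- list()
  for (fid in sort(unique(fam$family_id))) {
    members <- fam$gene_id[fam$family_id == fid]
    fa <- anchors |> filter(.data$gene_a %in% members)
    fa$ks <- unname(ks_map[paste(fa$gene_a, fa$gene_b)])
    known <- fa |> filter(!is.na(.data$ks))
    if (nrow(known) == 0) next
    if (length(members) == 2) {
      out[[fid]] <- tibble(family_id = fid, node_id = "N01",
                           gene_a = known$gene_a, gene_b = known$gene_b,
                           ks = known$ks, weight = 1, saturated = FALSE)
      next
    }
    pk <- known |>
      transmute(.data$gene_a, .data$gene_b, ks = pmin(.data$ks, ks_cap))
    # missing pairs within the family default to the cap for tree building
    dmat <- matrix(ks_cap, length(members), length(members),
                   dimnames = list(sort(members), sort(members)))
    diag(dmat) <- 0
    dmat[cbind(pk$gene_a, pk$gene_b)] <- pk$ks
    dmat[cbind(pk$gene_b, pk$gene_a)] <- pk$ks
    tree <- family_tree_alc(dmat, ks_cap = ks_cap)
    covered <- tree$pair_nodes |>
      semi_join(pk, by = c("gene_a", "gene_b"))
    full_pk <- tree$pair_nodes |>
      left_join(pk, by = c("gene_a", "gene_b")) |>
      mutate(ks = ifelse(is.na(.data$ks), ks_cap, .data$ks)) |>
      select("gene_a", "gene_b", "ks")
    dd <- deduplicate_ks(tree, full_pk, mode = mode)
    if (mode == "node_weighted") {
      dd <- dd |> semi_join(covered, by = c("gene_a", "gene_b"))
    }
    dd$family_id <- fid
    dd$saturated <- FALSE
    out[[fid]] <- dd[, c("family_id", "node_id", "gene_a", "gene_b", "ks",
                         "weight", "saturated")]
  }
  if (length(out) == 0) return(empty)
  purrr::list_rbind(out)
}

#' Write a segment table with one row per anchor pair
#'
#' The format round-trips through [read_segments_tsv()] and matches the
#' shape of externally produced (e.g. i-ADHoRe-style) segment listings.
#'
#' @param segments Segment tibble from [detect_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  flat <- segments |>
    select("segment_id", "chrom_a", "start_rank_a", "end_rank_a",
           "chrom_b", "start_rank_b", "end_rank_b", "anchors") |>
    tidyr::unnest("anchors") |>
    select("segment_id", "chrom_a", "start_rank_a", "end_rank_a",
           "chrom_b", "start_rank_b", "end_rank_b", "gene_a", "gene_b")
  readr::write_tsv(flat, path)
  invisible(path)
}
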