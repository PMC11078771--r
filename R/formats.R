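#' Read a FASTA file into a tibble
#'
#' Reads CDS or protein sequences. Sequence ids must be unique within the
#' file; the id is the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), seq = character()))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble(id = ids, seq = unname(as.character(set)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for the sequence blocks.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  lines <- unlist(purrr::map2(seqs$id, seqs$seq, function(id, s) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Extracts one locus per row of the selected feature type and converts the
#' GFF3 1-based inclusive coordinates to the internal 0-based half-open
#' convention (`start - 1`, `end`). Genes are ranked along each chromosome by
#' ascending start, ties broken by gene id.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type (column 3) to select. Default `"gene"`.
#' @param attribute_key Attribute key holding the gene id. Default `"ID"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`. `rank` is dense 0..(n-1) within each chromosome.
#' @export
read_gff_genes <- function(path, feature = "gene", attribute_key = "ID") {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  raw <- readr::read_lines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  line_no <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    abort(paste0("malformed GFF3 row (expected 9 columns) at line ",
                 line_no[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  sel <- m[, 3L] == feature
  if (!any(sel)) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character(),
                  rank = integer()))
  }
  m <- m[sel, , drop = FALSE]
  sel_lines <- line_no[sel]
  pat <- paste0("(?:^|;)\\s*", attribute_key, "=([^;]+)")
  mt <- regmatches(m[, 9L], regexec(pat, m[, 9L]))
  ids <- vapply(mt, function(x) if (length(x) == 2L) x[2] else NA_character_,
                character(1))
  if (anyNA(ids)) {
    abort(paste0("attribute '", attribute_key, "' missing on line ",
                 sel_lines[which(is.na(ids))[1]]))
  }
  start1 <- as.integer(m[, 4L]); end1 <- as.integer(m[, 5L])
  if (any(end1 < start1)) {
    abort(paste0("end < start at line ", sel_lines[which(end1 < start1)[1]]))
  }
  loci <- tibble(
    gene_id = ids, chromosome = m[, 1L],
    start = start1 - 1L, end = end1,
    strand = ifelse(m[, 7L] %in% c("+", "-"), m[, 7L], "+")
  )
  index_ranks(loci)
}

#' Assign dense per-chromosome gene ranks
#'
#' Orders genes along each chromosome by ascending start (ties broken by
#' gene id) and assigns 0-based dense ranks.
#'
#' @param loci A tibble with at least `gene_id`, `chromosome`, `start`.
#' @return The tibble with a `rank` column, sorted by chromosome and rank.
#' @export
index_ranks <- function(loci) {
  loci |>
    arrange(.data$chromosome, .data$start, .data$gene_id) |>
    group_by(.data$chromosome) |>
    mutate(rank = dplyr::row_number() - 1L) |>
    ungroup()
}

#' Write gene loci to a GFF3 file
#'
#' Inverse of [read_gff_genes()]: internal 0-based half-open coordinates are
#' written as GFF3 1-based inclusive.
#'
#' @param loci Tibble as returned by [read_gff_genes()].
#' @param path Output path.
#' @param feature Feature type to write. Default `"gene"`.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(loci, path, feature = "gene", source = "ksage") {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   loci$chromosome, source, feature,
                   loci$start + 1L, loci$end, loci$strand, loci$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

hit_cols <- c("query", "target", "identity", "length", "mismatches",
              "gapopens", "qstart", "qend", "tstart", "tend",
              "evalue", "bitscore")

#' Read an all-vs-all similarity hit table
#'
#' Reads 12-column tab-separated hits (query, target, identity, alignment
#' length, mismatches, gap opens, qstart, qend, tstart, tend, e-value,
#' bit-score), attaches amino-acid gene lengths, computes the proxy gene
#' length (product of query and target lengths), drops self-hits, and
#' de-duplicates reciprocal rows keeping the higher bit-score (ties keep the
#' lexicographically smaller (query, target)).
#'
#' @param path Path to the tabular hits file (no header).
#' @param lengths Named numeric/integer vector or tibble (`id`, `length`)
#'   mapping gene id to amino-acid length.
#' @return A tibble of hits with `proxy_len` and placeholder `norm_score`
#'   (`NA` until [normalize_bitscores()]).
#' @export
read_hits <- function(path, lengths) {
  if (!file.exists(path)) abort(paste0("hits file not found: ", path))
  if (is.data.frame(lengths)) lengths <- setNames(lengths$length, lengths$id)
  raw <- readr::read_lines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) {
    warn("empty hits file")
    return(empty_hits())
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0) {
    abort(paste0("malformed hits row (expected 12 columns) at line ", bad[1]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- tibble(
    query = m[, 1L], target = m[, 2L],
    identity = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gapopens = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    tstart = as.integer(m[, 9L]), tend = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L])
  )
  missing <- setdiff(unique(c(hits$query, hits$target)), names(lengths))
  if (length(missing) > 0) {
    abort(paste0("gene id(s) missing from lengths: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  hits <- hits |>
    filter(.data$query != .data$target) |>
    mutate(
      qlen = as.integer(lengths[.data$query]),
      tlen = as.integer(lengths[.data$target]),
      proxy_len = as.numeric(.data$qlen) * as.numeric(.data$tlen),
      norm_score = NA_real_
    )
  dedup_hits(hits)
}

# keep one row per unordered gene pair: higher bitscore wins, ties keep the
# lexicographically smaller (query, target)
dedup_hits <- function(hits) {
  hits |>
    mutate(
      .a = pmin(.data$query, .data$target),
      .b = pmax(.data$query, .data$target)
    ) |>
    arrange(.data$.a, .data$.b, desc(.data$bitscore), .data$query, .data$target) |>
    distinct(.data$.a, .data$.b, .keep_all = TRUE) |>
    select(-".a", -".b")
}

empty_hits <- function() {
  tibble(query = character(), target = character(), identity = numeric(),
         length = integer(), mismatches = integer(), gapopens = integer(),
         qstart = integer(), qend = integer(), tstart = integer(),
         tend = integer(), evalue = numeric(), bitscore = numeric(),
         qlen = integer(), tlen = integer(), proxy_len = numeric(),
         norm_score = numeric())
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Tibble of hits (the 12 standard columns are written; derived
#'   columns are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, hit_cols], path, col_names = FALSE)
  invisible(path)
}

#' Write a tibble as a deterministic TSV with header
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a collinear-segment table (i-ADHoRe-style import path)
#'
#' Accepts a TSV with columns `segment_id`, `chrom_a`, `start_rank_a`,
#' `end_rank_a`, `chrom_b`, `start_rank_b`, `end_rank_b`, `gene_a`, `gene_b`
#' (one row per anchor pair) and rebuilds the segment tibble used by the
#' collinearity functions.
#'
#' @param path Path to the TSV.
#' @return A segments tibble as returned by [detect_segments()].
#' @export
read_segments_tsv <- function(path) {
  rows <- readr::read_tsv(path, show_col_types = FALSE)
  rows |>
    tidyr::nest(anchors = c("gene_a", "gene_b")) |>
    group_by(.data$segment_id, .data$chrom_a, .data$chrom_b) |>
    summarise(
      start_rank_a = min(.data$start_rank_a),
      end_rank_a = max(.data$end_rank_a),
      start_rank_b = min(.data$start_rank_b),
      end_rank_b = max(.data$end_rank_b),
      anchors = list(bind_rows(.data$anchors)),
      .groups = "drop"
    ) |>
    mutate(n_anchors = purrr::map_int(.data$anchors, nrow), intra = TRUE)
}
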