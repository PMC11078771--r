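#' Mode of a (weighted) Gaussian kernel density estimate
#'
#' The density is evaluated on a fixed grid of `n_grid` points over
#' `[0, max(values) * 1.05]`; the mode is the grid argmax (left-most on
#' ties). The default bandwidth is Silverman's rule computed on the weighted
#' sample.
#'
#' @param values Non-negative numeric values (at least 5, unless all equal).
#' @param weights Optional non-negative weights.
#' @param bandwidth Numeric bandwidth, or `NULL` for weighted Silverman.
#' @param n_grid Grid size. Default 512.
#' @return The mode (a single numeric value).
#' @export
kde_mode <- function(values, weights = NULL, bandwidth = NULL, n_grid = 512) {
  if (any(values < 0)) abort("kde_mode requires non-negative values")
  if (length(unique(values)) == 1) return(values[1])
  if (length(values) < 5) abort("kde_mode needs at least 5 values")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (is.null(bandwidth)) bandwidth <- bw_silverman_weighted(values, weights)
  d <- density(values, bw = bandwidth, weights = weights / sum(weights),
               from = 0, to = max(values) * 1.05, n = n_grid)
  d$x[which.max(d$y)]
}

# Silverman's rule of thumb on a weighted sample, with the effective sample
# size (sum w)^2 / sum w^2 in place of n
bw_silverman_weighted <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sigma <- sqrt(sum(w * (x - mu)^2))
  iqr <- weighted_quantile(x, w, 0.75) - weighted_quantile(x, w, 0.25)
  n_eff <- 1 / sum(w^2)
  spread <- min(sigma, iqr / 1.34)
  if (spread <= 0) spread <- max(sigma, 1e-3)
  0.9 * spread * n_eff^(-1 / 5)
}

weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= p)[1]]
}

#' Bootstrap the KDE mode of a Ks distribution
#'
#' Resamples the values with replacement (probability proportional to weight)
#' to the original size `n_boot` times and records the KDE mode of each
#' replicate.
#'
#' @param values Ks values (at least 5).
#' @param weights Optional weights (node-weighted distributions).
#' @param n_boot Number of replicates. Default 200.
#' @param seed Integer seed.
#' @param ... Passed to [kde_mode()].
#' @return An object of class `ksage_boot`: `modes` (length `n_boot`),
#'   `mean_mode`, `sd_mode`, `ci90`, `raw_mode` (mode of the unresampled
#'   data).
#' @export
bootstrap_modes <- function(values, weights = NULL, n_boot = 200,
                            seed = NULL, ...) {
  if (length(values) < 5) abort("bootstrap_modes needs at least 5 values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  prob <- if (is.null(weights)) NULL else weights / sum(weights)
  modes <- vapply(seq_len(n_boot), function(b) {
    kde_mode(values[sample.int(n, n, replace = TRUE, prob = prob)], ...)
  }, numeric(1))
  structure(list(
    modes = modes,
    mean_mode = mean(modes),
    sd_mode = sd(modes),
    ci90 = unname(quantile(modes, c(0.05, 0.95))),
    raw_mode = kde_mode(values, weights, ...),
    n_boot = n_boot
  ), class = "ksage_boot")
}

#' Canonical key for a species pair
#'
#' @param a,b Species labels.
#' @return `"<first>__<second>"` with the labels sorted.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "__")
}

#' Rescale a divergence mode across trios and propagate its uncertainty
#'
#' For every outgroup, the trio's rescaled replicate is
#' `mode(focal, outgroup) - mode(sister, outgroup) + mode(focal, sister)`,
#' paired by bootstrap replicate index. The rescaled mode is the mean over
#' replicates and trios; its standard deviation combines the per-trio
#' variances with the covariances across trios (which share the
#' focal-sister bootstrap stream):
#' `std = sqrt(sum(Var_i) + 2 * sum_{i<j} Cov_ij) / N`.
#'
#' @param pair_modes Named list of [bootstrap_modes()] results, keyed by
#'   [pair_key()] of the species pair. Must cover (focal, sister) and both
#'   pairs with every outgroup, all with the same `n_boot`.
#' @param focal,sister Species labels.
#' @param outgroups Character vector of outgroup species labels.
#' @return An object of class `ksage_correction`: `rescaled_mode`, `std`,
#'   `trios` (per-outgroup tibble with trio means and variances),
#'   `cov_matrix`, `replicates` (n_boot x N matrix), plus the inputs.
#' @export
rescale_trios <- function(pair_modes, focal, sister, outgroups) {
  if (length(outgroups) == 0) abort("no outgroups: N == 0")
  get_modes <- function(a, b) {
    key <- pair_key(a, b)
    bm <- pair_modes[[key]]
    if (is.null(bm)) abort(paste0("missing bootstrap modes for pair ", key))
    bm$modes
  }
  m_fs <- get_modes(focal, sister)
  reps <- vapply(outgroups, function(o) {
    m_fo <- get_modes(focal, o)
    m_so <- get_modes(sister, o)
    if (length(m_fo) != length(m_fs) || length(m_so) != length(m_fs)) {
      abort("bootstrap replicate counts differ across pairs")
    }
    m_fo - m_so + m_fs
  }, numeric(length(m_fs)))
  reps <- matrix(reps, nrow = length(m_fs),
                 dimnames = list(NULL, outgroups))
  n_trios <- ncol(reps)
  trio_means <- colMeans(reps)
  cov_matrix <- cov(reps)
  if (any(trio_means < 0)) warn("negative rescaled trio mode")
  rescaled_mode <- mean(trio_means)
  std <- sqrt(sum(cov_matrix)) / n_trios
  structure(list(
    focal = focal, sister = sister, outgroups = outgroups,
    rescaled_mode = rescaled_mode, std = std,
    trios = tibble(outgroup = outgroups,
                   rescaled_mode_trio = unname(trio_means),
                   var_trio = unname(diag(cov_matrix))),
    cov_matrix = cov_matrix,
    replicates = reps,
    n_boot = nrow(reps)
  ), class = "ksage_correction")
}

#' @export
print.ksage_correction <- function(x, ...) {
  cat(sprintf("Rate-corrected divergence of (%s, %s): rescaled mode %.4f +/- %.4f (std)\n",
              x$focal, x$sister, x$rescaled_mode, x$std))
  cat(sprintf("  %d trio(s), %d bootstrap replicates\n",
              length(x$outgroups), x$n_boot))
  invisible(x)
}
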