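# Weighted EM machinery for Ks mixture models. Data weights (node-weighted
# distributions) multiply the responsibilities in every sufficient statistic.

# extract positive, finite Ks values and weights from a vector or a
# WeightedKsDistribution-style tibble; reports exclusions
ks_input <- function(ks, weights = NULL) {
  if (is.data.frame(ks)) {
    weights <- if ("weight" %in% names(ks)) ks$weight else NULL
    sat <- if ("saturated" %in% names(ks)) ks$saturated else FALSE
    x <- ks$ks
    drop_sat <- sat %in% TRUE
  } else {
    x <- as.numeric(ks)
    drop_sat <- rep(FALSE, length(x))
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  keep <- is.finite(x) & x > 0 & !drop_sat
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0(n_dropped,
                  " non-positive, non-finite or saturated Ks value(s) excluded"))
  }
  list(x = x[keep], w = weights[keep], n_excluded = n_dropped)
}

new_mixture_fit <- function(kind, components, exp_rate, exp_weight, loglik,
                            n_used, sum_w, n_iter, converged, trace) {
  k_free <- if (kind == "elmm") {
    m <- nrow(components)
    if (m == 0) 1 else 3 * m + 1
  } else {
    3 * nrow(components) - 1
  }
  structure(list(
    kind = kind,
    components = components,
    exp_rate = exp_rate,
    exp_weight = exp_weight,
    loglik = loglik,
    bic = -2 * loglik + k_free * log(n_used),
    aic = -2 * loglik + 2 * k_free,
    k_free = k_free,
    n_used = n_used,
    sum_weight = sum_w,
    n_iter = n_iter,
    converged = converged,
    loglik_trace = trace
  ), class = "ksage_mixture")
}

#' @export
print.ksage_mixture <- function(x, ...) {
  cat(sprintf("%s mixture fit: %d lognormal component(s)%s\n",
              toupper(x$kind), nrow(x$components),
              if (x$kind == "elmm") sprintf(" + exponential background (rate %.3f, weight %.3f)",
                                            x$exp_rate, x$exp_weight) else ""))
  cat(sprintf("  loglik %.2f  BIC %.2f  AIC %.2f  (n = %d, %s after %d iterations)\n",
              x$loglik, x$bic, x$aic, x$n_used,
              if (x$converged) "converged" else "not converged", x$n_iter))
  if (nrow(x$components) > 0) print.data.frame(as.data.frame(x$components))
  invisible(x)
}

#' Fit log-scale Gaussian mixture models to a Ks distribution
#'
#' Fits a Gaussian mixture to `log(Ks)` by weighted EM for each candidate
#' number of components; on the Ks scale each component is a lognormal whose
#' mode (`peak`) is `exp(log_mean - log_sd^2)`. Zero and saturated Ks values
#' are excluded (with a message) before the log transform.
#'
#' @param ks Numeric Ks values, or a tibble with `ks` (and optionally
#'   `weight`, `saturated`) columns.
#' @param k_range Integer vector of component counts to fit. Default `1:3`.
#' @param weights Optional weights (ignored when `ks` is a tibble with a
#'   `weight` column).
#' @param n_init Random initializations per k (best log-likelihood kept).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the log-likelihood. Default 1e-6.
#' @param max_iter Maximum EM iterations. Default 500.
#' @return A list of `ksage_mixture` fits, one per `k` (skipped k's with a
#'   warning when fewer than `5 * k` points are available).
#' @export
fit_gmm_log <- function(ks, k_range = 1:3, weights = NULL, n_init = 5,
                        seed = NULL, tol = 1e-6, max_iter = 500) {
  inp <- ks_input(ks, weights)
  if (length(inp$x) == 0) abort("no usable Ks values")
  if (!is.null(seed)) set.seed(seed)
  y <- log(inp$x)
  w <- inp$w
  fits <- list()
  for (k in k_range) {
    if (length(y) < 5 * k) {
      warn(paste0("k = ", k, " skipped: fewer than ", 5 * k, " values"))
      next
    }
    best <- NULL
    for (init in seq_len(n_init)) {
      f <- em_gmm(y, w, k, init, tol, max_iter)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (isTRUE(best$floor_hit)) {
      warn("a component log_sd hit the floor (1e-3); degenerate data")
    }
    comps <- tibble(
      component = seq_len(k),
      weight = best$pi,
      log_mean = best$mu,
      log_sd = best$sd,
      peak = exp(best$mu - best$sd^2)
    ) |> arrange(.data$log_mean) |> mutate(component = dplyr::row_number())
    fits[[length(fits) + 1]] <- new_mixture_fit(
      "gmm_log", comps, NA_real_, 0, best$loglik,
      n_used = length(y), sum_w = sum(w), n_iter = best$n_iter,
      converged = best$converged, trace = best$trace
    )
  }
  fits
}

em_gmm <- function(y, w, k, init, tol, max_iter) {
  qs <- weighted_quantile_vec(y, w, (seq_len(k) - 0.5) / k)
  mu <- qs + if (init == 1) 0 else stats::rnorm(k, 0, sd(y) / 4)
  sdev <- rep(max(sd(y), 1e-2), k)
  pi_k <- rep(1 / k, k)
  W <- sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  floor_hit <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      dnorm(y, mu[j], sdev[j]) * pi_k[j]
    }, numeric(length(y)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    wr <- resp * w
    Nk <- colSums(wr)
    pi_k <- Nk / W
    mu <- colSums(wr * y) / Nk
    sdev <- sqrt(pmax(colSums(wr * (y - matrix(mu, length(y), k,
                                               byrow = TRUE))^2) / Nk, 0))
    if (any(sdev < 1e-3)) {
      sdev <- pmax(sdev, 1e-3)
      floor_hit <- TRUE
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, sd = sdev, loglik = trace[length(trace)],
       n_iter = length(trace), converged = converged, trace = trace,
       floor_hit = floor_hit)
}

weighted_quantile_vec <- function(x, w, ps) {
  vapply(ps, function(p) weighted_quantile(x, w, p), numeric(1))
}

#' Fit exponential-lognormal mixture models to a Ks distribution
#'
#' The background of small-scale duplications is an exponential on the Ks
#' scale; WGD peaks are lognormal components (normals in log space). Models
#' with 0..`max_lognormals` lognormal components are fitted by weighted EM
#' and returned with BIC/AIC for model selection.
#'
#' @inheritParams fit_gmm_log
#' @param max_lognormals Maximum number of lognormal peaks. Default 5.
#' @return A list of `ksage_mixture` fits, one per component count `m`
#'   in `0:max_lognormals` (skipping m's with fewer than `5 * (m + 1)`
#'   points).
#' @export
fit_elmm <- function(ks, max_lognormals = 5, weights = NULL, n_init = 5,
                     seed = NULL, tol = 1e-6, max_iter = 500) {
  inp <- ks_input(ks, weights)
  if (length(inp$x) == 0) abort("no usable Ks values")
  if (!is.null(seed)) set.seed(seed)
  x <- inp$x
  w <- inp$w
  fits <- list()
  for (m in 0:max_lognormals) {
    if (length(x) < 5 * (m + 1)) {
      warn(paste0("m = ", m, " skipped: too few values"))
      next
    }
    best <- NULL
    for (init in seq_len(n_init)) {
      f <- em_elmm(x, w, m, init, tol, max_iter)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    comps <- if (m == 0) {
      tibble(component = integer(), weight = numeric(),
             log_mean = numeric(), log_sd = numeric(), peak = numeric())
    } else {
      tibble(component = seq_len(m), weight = best$pi_ln,
             log_mean = best$mu, log_sd = best$sd,
             peak = exp(best$mu - best$sd^2)) |>
        arrange(.data$log_mean) |> mutate(component = dplyr::row_number())
    }
    if (!best$converged) {
      warn(paste0("ELMM with m = ", m,
                  " did not converge; best-so-far returned"))
    }
    fits[[length(fits) + 1]] <- new_mixture_fit(
      "elmm", comps, best$rate, best$pi_bg, best$loglik,
      n_used = length(x), sum_w = sum(w), n_iter = best$n_iter,
      converged = best$converged, trace = best$trace
    )
  }
  fits
}

em_elmm <- function(x, w, m, init, tol, max_iter) {
  lx <- log(x)
  rate <- 1 / weighted.mean(x, w)
  if (m > 0) {
    qs <- weighted_quantile_vec(lx, w, (seq_len(m) - 0.5) / m)
    mu <- qs + if (init == 1) 0 else stats::rnorm(m, 0, max(sd(lx) / 4, 1e-2))
    sdev <- rep(max(sd(lx) / 2, 0.05), m)
    pi_bg <- 0.5
    pi_ln <- rep(0.5 / m, m)
  } else {
    mu <- numeric(0); sdev <- numeric(0); pi_ln <- numeric(0); pi_bg <- 1
  }
  W <- sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- matrix(0, length(x), m + 1)
    dens[, 1] <- pi_bg * dexp(x, rate)
    for (j in seq_len(m)) {
      dens[, j + 1] <- pi_ln[j] * dlnorm(x, mu[j], sdev[j])
    }
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    wr <- resp * w
    Nk <- colSums(wr)
    pi_all <- Nk / W
    pi_bg <- pi_all[1]
    rate <- Nk[1] / sum(wr[, 1] * x)
    if (!is.finite(rate) || rate <= 0) rate <- 1 / weighted.mean(x, w)
    if (m > 0) {
      pi_ln <- pi_all[-1]
      for (j in seq_len(m)) {
        if (Nk[j + 1] <= 1e-12) next
        mu[j] <- sum(wr[, j + 1] * lx) / Nk[j + 1]
        sdev[j] <- sqrt(max(sum(wr[, j + 1] * (lx - mu[j])^2) / Nk[j + 1],
                            1e-6))
      }
      sdev <- pmax(sdev, 1e-3)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(rate = rate, pi_bg = pi_bg, pi_ln = pi_ln, mu = mu, sd = sdev,
       loglik = trace[length(trace)], n_iter = length(trace),
       converged = converged, trace = trace)
}

#' Select a mixture fit by information criterion
#'
#' @param fits A list of `ksage_mixture` fits.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return The converged fit with the lowest criterion value; ties go to the
#'   model with fewer components.
#' @export
select_model <- function(fits, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  conv <- purrr::keep(fits, function(f) isTRUE(f$converged))
  if (length(conv) == 0) {
    diag <- purrr::map_chr(fits, function(f) {
      sprintf("%s m=%d loglik=%.2f n_iter=%d", f$kind, nrow(f$components),
              f$loglik, f$n_iter)
    })
    abort(paste0("no converged mixture fit:\n", paste(diag, collapse = "\n")))
  }
  crit <- purrr::map_dbl(conv, criterion)
  ncomp <- purrr::map_int(conv, function(f) nrow(f$components))
  conv[[order(round(crit, 8), ncomp)[1]]]
}

#' Filter anchor pairs by the confidence interval of a fitted WGD peak
#'
#' Keeps anchor pairs whose Ks lies within the central `level` quantile
#' interval of the chosen lognormal component,
#' `exp(log_mean +/- z * log_sd)`, with the upper bound truncated at the Ks
#' saturation cutoff.
#'
#' @param anchor_ks A tibble with a `ks` column and a pair identifier column
#'   (`pair_id`, or `gene_a`/`gene_b` which are combined).
#' @param fit A `ksage_mixture` fit holding lognormal components.
#' @param component_index Which component is the WGD peak. Default 1.
#' @param level Central confidence level in (0, 1). Default 0.95.
#' @param ks_cutoff Saturation cutoff truncating the upper bound. Default 3.
#' @return An object of class `ksage_peak_filter`: `component`, `level`,
#'   `interval`, `ks_cutoff`, `retained` (tibble of retained pairs),
#'   `n_input`, `n_retained`.
#' @export
filter_anchors <- function(anchor_ks, fit, component_index = 1,
                           level = 0.95, ks_cutoff = 3) {
  stopifnot(level > 0, level < 1)
  comp <- fit$components
  if (component_index < 1 || component_index > nrow(comp)) {
    abort("component_index out of range for this fit")
  }
  comp <- comp[component_index, ]
  z <- qnorm(1 - (1 - level) / 2)
  lo <- exp(comp$log_mean - z * comp$log_sd)
  hi <- min(exp(comp$log_mean + z * comp$log_sd), ks_cutoff)
  if (hi <= lo) {
    abort(paste0("empty retention interval after ks_cutoff ", ks_cutoff,
                 "; consider a lower component"))
  }
  ak <- as_tibble(anchor_ks)
  if (!"pair_id" %in% names(ak)) {
    if (all(c("gene_a", "gene_b") %in% names(ak))) {
      ak$pair_id <- paste(pmin(ak$gene_a, ak$gene_b),
                          pmax(ak$gene_a, ak$gene_b), sep = "__")
    } else {
      ak$pair_id <- as.character(seq_len(nrow(ak)))
    }
  }
  retained <- ak |> filter(.data$ks >= lo, .data$ks <= hi)
  structure(list(
    component = comp, level = level, interval = c(lo = lo, hi = hi),
    ks_cutoff = ks_cutoff, retained = retained,
    n_input = nrow(ak), n_retained = nrow(retained)
  ), class = "ksage_peak_filter")
}

#' @export
print.ksage_peak_filter <- function(x, ...) {
  cat(sprintf("Anchor-pair peak filter: %.0f%% interval (%.4f, %.4f), kscutoff %g\n",
              100 * x$level, x$interval[1], x$interval[2], x$ks_cutoff))
  cat(sprintf("  retained %d of %d pairs\n", x$n_retained, x$n_input))
  invisible(x)
}

#' Export orthogroup alignments and a dating control template
#'
#' Writes, per orthogroup, a FASTA file of the members' coding sequences,
#' plus the annotated species tree (Newick) and a control-file template for
#' an external molecular-dating engine. No engine is executed.
#'
#' @param orthogroups Tibble from [assemble_dating_orthogroups()].
#' @param cds CDS tibble (`id`, `seq`).
#' @param species_tree A Newick string (calibration annotations are passed
#'   through verbatim).
#' @param outdir Output directory (created if needed).
#' @return A tibble of written files (`orthogroup_id`, `path`); the tree and
#'   control template are listed with id `NA`.
#' @export
export_dating_inputs <- function(orthogroups, cds, species_tree, outdir) {
  if (nrow(orthogroups) == 0) abort("no orthogroups to export")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seqs <- setNames(cds$seq, cds$id)
  files <- list()
  for (og in sort(unique(orthogroups$orthogroup_id))) {
    members <- orthogroups |> filter(.data$orthogroup_id == og)
    if (!all(members$gene_id %in% names(seqs))) {
      inform(paste0("orthogroup ", og, " skipped: missing CDS"))
      next
    }
    path <- file.path(outdir, paste0(og, ".fasta"))
    write_fasta(tibble(id = members$gene_id,
                       seq = unname(seqs[members$gene_id])), path)
    files[[length(files) + 1]] <- tibble(orthogroup_id = og, path = path)
  }
  if (length(files) == 0) abort("no orthogroup had complete CDS coverage")
  tree_path <- file.path(outdir, "dating_tree.nwk")
  writeLines(species_tree, tree_path)
  ctl_path <- file.path(outdir, "dating_control.txt")
  writeLines(c(
    "# molecular dating control template (fill in engine-specific settings)",
    paste0("treefile = ", basename(tree_path)),
    "alignments = *.fasta",
    "clock = independent-rates",
    "burnin = 10000",
    "nsample = 20000",
    "sampfreq = 10"
  ), ctl_path)
  bind_rows(
    purrr::list_rbind(files),
    tibble(orthogroup_id = NA_character_, path = c(tree_path, ctl_path))
  )
}
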