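#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture fit into its component table
#'
#' @param x A `ksage_mixture`.
#' @param ... Unused.
#' @return A tibble with one row per component (`component`, `weight`,
#'   `log_mean`, `log_sd`, `peak`); for ELMM fits the exponential background
#'   appears as `component = 0` with `exp_rate` filled.
#' @method tidy ksage_mixture
#' @export
tidy.ksage_mixture <- function(x, ...) {
  comps <- x$components |> mutate(exp_rate = NA_real_)
  if (x$kind == "elmm") {
    bg <- tibble(component = 0L, weight = x$exp_weight,
                 log_mean = NA_real_, log_sd = NA_real_, peak = NA_real_,
                 exp_rate = x$exp_rate)
    comps <- bind_rows(bg, comps)
  }
  comps
}

#' One-row summary of a mixture fit
#'
#' @param x A `ksage_mixture`.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `n_components`, `loglik`, `bic`, `aic`,
#'   `n_used`, `n_iter`, `converged`.
#' @method glance ksage_mixture
#' @export
glance.ksage_mixture <- function(x, ...) {
  tibble(kind = x$kind, n_components = nrow(x$components),
         loglik = x$loglik, bic = x$bic, aic = x$aic,
         n_used = x$n_used, n_iter = x$n_iter, converged = x$converged)
}

#' One-row summary of a bit-score normalization fit
#'
#' @param x A `ksage_norm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the regression parameters and the
#'   before/after R-squared of bit-score on gene length.
#' @method glance ksage_norm_fit
#' @export
glance.ksage_norm_fit <- function(x, ...) {
  tibble(n_bins = x$n_bins, top_percent = x$top_percent,
         slope = x$slope, intercept = x$intercept,
         r_squared_upper = x$r_squared_upper,
         r_squared_all_before = x$r_squared_all_before,
         r_squared_all_after = x$r_squared_all_after,
         n_hits = x$n_hits, n_selected = x$n_selected)
}

#' Tidy a rate correction into its per-trio table
#'
#' @param x A `ksage_correction`.
#' @param ... Unused.
#' @return The per-outgroup trio tibble (`outgroup`, `rescaled_mode_trio`,
#'   `var_trio`).
#' @method tidy ksage_correction
#' @export
tidy.ksage_correction <- function(x, ...) x$trios

#' One-row summary of a rate correction
#'
#' @param x A `ksage_correction`.
#' @param ... Unused.
#' @return A one-row tibble: `focal`, `sister`, `n_trios`, `rescaled_mode`,
#'   `std`, `n_boot`.
#' @method glance ksage_correction
#' @export
glance.ksage_correction <- function(x, ...) {
  tibble(focal = x$focal, sister = x$sister,
         n_trios = length(x$outgroups),
         rescaled_mode = x$rescaled_mode, std = x$std, n_boot = x$n_boot)
}
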