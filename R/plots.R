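#' Plot a weighted Ks age distribution
#'
#' Weighted histogram of the Ks values, optionally overlaid with the density
#' of a fitted mixture (scaled to the histogram area).
#'
#' @param ks A tibble with `ks` (and optionally `weight`) columns, or a
#'   numeric vector.
#' @param fit Optional `ksage_mixture` to overlay.
#' @param binwidth Histogram bin width. Default 0.05.
#' @param ks_max Upper display limit. Default 5.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(ks, fit = NULL, binwidth = 0.05, ks_max = 5) {
  inp <- ks_input(ks)
  d <- tibble(ks = inp$x, weight = inp$w) |> filter(.data$ks <= ks_max)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ks,
                                       weight = .data$weight)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey40",
                            linewidth = 0.1) +
    ggplot2::labs(x = expression(K[s]), y = "weighted count") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    total <- sum(d$weight) * binwidth
    grid <- seq(1e-3, ks_max, length.out = 512)
    dens <- mixture_density(fit, grid)
    dens$y <- dens$y * total
    p <- p +
      ggplot2::geom_line(data = dens,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$component),
                         inherit.aes = FALSE) +
      ggplot2::labs(colour = "component")
  }
  p
}

# per-component density of a mixture fit on a Ks grid
mixture_density <- function(fit, grid) {
  out <- list()
  if (fit$kind == "elmm") {
    out[[1]] <- tibble(x = grid, y = fit$exp_weight * dexp(grid, fit$exp_rate),
                       component = "background")
  }
  for (j in seq_len(nrow(fit$components))) {
    cj <- fit$components[j, ]
    out[[length(out) + 1]] <- tibble(
      x = grid, y = cj$weight * dlnorm(grid, cj$log_mean, cj$log_sd),
      component = paste0("lognormal_", cj$component)
    )
  }
  total <- purrr::list_rbind(out) |>
    group_by(.data$x) |>
    summarise(y = sum(.data$y), .groups = "drop") |>
    mutate(component = "total")
  bind_rows(purrr::list_rbind(out), total)
}

#' @rdname plot_ks_distribution
#' @param object A `ksage_mixture` fit.
#' @param ... Passed on to [plot_ks_distribution()] (`ks` is required).
#' @method autoplot ksage_mixture
#' @export
autoplot.ksage_mixture <- function(object, ks, ...) {
  plot_ks_distribution(ks, fit = object, ...)
}

#' Gene homology dot plot
#'
#' @param dots A tibble from [dotplot_table()].
#' @return A ggplot object; anchor pairs are coloured by Ks when available.
#' @export
plot_dotplot <- function(dots) {
  ggplot2::ggplot(dots, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = dots |> filter(!.data$is_anchor),
                        size = 0.3, colour = "grey75") +
    ggplot2::geom_point(data = dots |> filter(.data$is_anchor),
                        ggplot2::aes(colour = .data$ks), size = 0.5) +
    ggplot2::scale_colour_viridis_c(na.value = "black") +
    ggplot2::labs(x = "gene index (genome a)", y = "gene index (genome b)",
                  colour = expression(K[s])) +
    ggplot2::theme_minimal()
}

#' Stacked multiplicon intervals along chromosomes (dupstack plot)
#'
#' @param stack A tibble from [dupstack()].
#' @return A ggplot object with one facet per chromosome.
#' @export
plot_dupstack <- function(stack) {
  ggplot2::ggplot(stack,
                  ggplot2::aes(xmin = .data$start_bp, xmax = .data$end_bp,
                               ymin = .data$lane - 0.4,
                               ymax = .data$lane + 0.4,
                               fill = .data$scope)) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~chromosome, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "lane", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Multiplication-level profile (syndepth plot)
#'
#' @param profile A tibble from [syndepth()].
#' @return A ggplot bar chart of segment-group counts per multiplication
#'   level.
#' @export
plot_syndepth <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$level), y = .data$n_groups,
                               fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "multiplication level", y = "segment groups",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
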