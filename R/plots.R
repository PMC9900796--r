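#' Plot a per-parcel brain map on the centroid sphere
#'
#' Longitude/latitude projection of the parcel centroids colored by a map
#' value — the quick-look equivalent of a surface plot for centroid-level
#' data.
#'
#' @param geometry A `parcellation` tibble.
#' @param values Per-parcel numeric values (aligned to `geometry`).
#' @param label Legend title.
#' @return A `ggplot` object.
#' @export
plot_brain_map <- function(geometry, values, label = "value") {
  df <- tibble(
    lon = atan2(geometry$y, geometry$x),
    lat = asin(pmin(1, pmax(-1, geometry$z))),
    hemi = geometry$hemi,
    value = values
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   color = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~hemi) +
    ggplot2::scale_color_viridis_c(name = label) +
    ggplot2::labs(x = "longitude (rad)", y = "latitude (rad)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dyn_pca <- function(object, n_components = 10, ...) {
  k <- min(n_components, length(object$variance_fraction))
  df <- tibble(component = factor(seq_len(k)),
               variance = 100 * object$variance_fraction[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(y = "variance explained (%)",
                  title = "Principal components of the feature matrix") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dyn_pls <- function(object, ...) {
  df <- tibble(lv = factor(seq_along(object$effect_size)),
               effect = 100 * object$effect_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$lv, .data$effect)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "latent variable", y = "covariance explained (%)") +
    ggplot2::theme_minimal()
}

#' Loading plot with bootstrap confidence intervals
#'
#' @param boot Output of [pls_bootstrap_loadings()].
#' @param side `"x"` or `"y"`.
#' @param top_n Show the `top_n` largest absolute loadings.
#' @return A `ggplot` object.
#' @export
plot_pls_loadings <- function(boot, side = c("y", "x"), top_n = 20) {
  side <- match.arg(side)
  df <- boot %>%
    filter(.data$side == !!side) %>%
    arrange(dplyr::desc(abs(.data$loading))) %>%
    head(top_n) %>%
    mutate(name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(df, ggplot2::aes(.data$loading, .data$name)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(y = NULL, x = "loading (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}
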