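#' Density of rewiring capacity by trophic level
#'
#' @param capacity Tibble from [rewiring_capacity()] (one level) or a
#'   row-bound pair of them.
#' @return A ggplot.
#' @export
plot_capacity <- function(capacity) {
  ggplot2::ggplot(capacity,
                  ggplot2::aes(x = .data$fric_std,
                               fill = .data$trophic_level)) +
    ggplot2::geom_density(alpha = 0.5, bounds = c(0, 1)) +
    ggplot2::labs(x = "Rewiring capacity (standardized FRic)",
                  y = "Density", fill = "Trophic level") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Map of rewiring potential or its bivariate classes
#'
#' @param map Tibble from [potential_map()].
#' @param fill `"potential"` (continuous) or `"bivariate_class"` (the 3x3
#'   richness-by-potential legend).
#' @return A ggplot faceted by trophic level; cells with no species are
#'   blank (NA fill).
#' @export
plot_potential_map <- function(map, fill = c("potential", "bivariate_class")) {
  fill <- match.arg(fill)
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$lon, y = .data$lat))
  if (fill == "potential") {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$potential)) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85")
  } else {
    p <- p +
      ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$bivariate_class))) +
      ggplot2::scale_fill_brewer(palette = "RdYlBu", na.value = "grey85",
                                 name = "richness x potential\ntercile class")
  }
  p + ggplot2::facet_wrap(~trophic_level) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Partial-effect curve of richness on rewiring potential
#'
#' @param effect Tibble from [partial_effect()].
#' @return A ggplot with a 2-SE ribbon.
#' @export
plot_partial_effect <- function(effect) {
  ggplot2::ggplot(effect, ggplot2::aes(x = .data$richness, y = .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$effect - 2 * .data$se,
                                      ymax = .data$effect + 2 * .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Species richness",
                  y = "Partial effect on rewiring potential (centered)") +
    ggplot2::theme_minimal()
}

#' @method autoplot potential_gam
#' @export
autoplot.potential_gam <- function(object, ...) {
  plot_partial_effect(partial_effect(object, ...))
}

#' @method tidy link_model
#' @export
tidy.link_model <- function(x, ...) {
  x$importance
}

#' @method glance link_model
#' @export
glance.link_model <- function(x, ...) {
  tibble::tibble(
    n_rounds = x$n_rounds,
    learning_rate = x$params$learning_rate,
    max_depth = x$params$max_depth,
    bag_fraction = x$params$bag_fraction,
    n_features = length(x$feature_names)
  )
}

#' @method tidy link_cv
#' @export
tidy.link_cv <- function(x, ...) {
  x$metrics
}

#' @method glance link_cv
#' @export
glance.link_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(k = x$k, n = nrow(x$scores)),
                   x$metrics[1, ])
}
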