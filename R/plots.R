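#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster
#'
#' Continuous fill map of a single band on the pixel-centre grid.
#'
#' @param object an `et_raster`.
#' @param band band to draw (index) for multi-band rasters.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.et_raster <- function(object, band = 1L, ...) {
  df <- dplyr::filter(as_tibble(object), .data$band == !!band)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot the four flux bands of a model run
#'
#' @param object a `flux_raster` from [run_tseb()].
#' @param ... unused.
#' @return a ggplot faceted over Rn, H, LE and G.
#' @export
autoplot.flux_raster <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(band = factor(object$band_names[.data$band],
                                levels = object$band_names)) |>
    dplyr::filter(.data$band != "converged")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "W/m²") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Modelled vs measured scatter of a validation
#'
#' @param object an `et_validation` from [validation_stats()].
#' @param ... unused.
#' @return a ggplot with the 1:1 line and the OLS fit.
#' @export
autoplot.et_validation <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(.data$measured, .data$modelled)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "measured LE (W/m²)", y = "modelled LE (W/m²)",
                  subtitle = sprintf("RMSE %.1f, RMSD %.1f W/m², n = %d",
                                     object$rmse, object$rmsd, object$n))
  if (!object$degenerate)
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  colour = "steelblue")
  p
}
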