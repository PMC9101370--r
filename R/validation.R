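#' Eddy-covariance footprint disk
#'
#' The footprint of a half-hour flux record is represented by a disk of
#' `disk_diameter` metres centred at the footprint peak: the point
#' `peak_distance` metres from the tower along the upwind bearing.
#' `wind_direction` follows the meteorological convention (direction the
#' wind comes FROM, degrees clockwise from north), so the peak lies on that
#' bearing as seen from the tower.
#'
#' @param tower_x,tower_y tower position in the raster CRS (m).
#' @param wind_direction main wind direction, degrees from north, [0, 360).
#' @param peak_distance distance to the footprint peak, m (>= 0).
#' @param disk_diameter disk diameter, m (default 10).
#' @return a `footprint_spec` object.
#' @export
footprint_spec <- function(tower_x, tower_y, wind_direction, peak_distance,
                           disk_diameter = 10) {
  stopifnot(wind_direction >= 0, wind_direction < 360,
            peak_distance >= 0, disk_diameter > 0)
  structure(list(tower_x = tower_x, tower_y = tower_y,
                 wind_direction = wind_direction,
                 peak_distance = peak_distance,
                 disk_diameter = disk_diameter),
            class = "footprint_spec")
}

#' @rdname footprint_spec
#' @param spec a `footprint_spec`.
#' @return `footprint_center` returns `c(x, y)` of the disk centre.
#' @export
footprint_center <- function(spec) {
  brg <- spec$wind_direction * pi / 180
  c(x = spec$tower_x + spec$peak_distance * sin(brg),
    y = spec$tower_y + spec$peak_distance * cos(brg))
}

#' Rasterize a footprint disk
#'
#' Binary mask on the grid of `grid`: a pixel is inside when its centre
#' lies within the disk radius of the footprint centre.
#'
#' @param spec a [footprint_spec()].
#' @param grid an `et_raster` supplying the grid.
#' @return logical-valued `et_raster` (1 inside, 0 outside).
#' @export
footprint_disk <- function(spec, grid) {
  stopifnot(inherits(spec, "footprint_spec"), inherits(grid, "et_raster"))
  ctr <- footprint_center(spec)
  ext <- raster_extent(grid)
  r <- spec$disk_diameter / 2
  if (ctr["x"] + r < ext["xmin"] || ctr["x"] - r > ext["xmax"] ||
      ctr["y"] + r < ext["ymin"] || ctr["y"] - r > ext["ymax"])
    stop(sprintf("footprint disk at (%.1f, %.1f) r=%.1f m does not intersect raster extent [%g, %g] x [%g, %g]",
                 ctr["x"], ctr["y"], r,
                 ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
  xy <- raster_xy(grid)
  dx <- outer(rep(1, length(xy$y)), xy$x - ctr["x"])
  dy <- outer(xy$y - ctr["y"], rep(1, length(xy$x)))
  mask <- (dx^2 + dy^2) <= r^2
  et_raster(mask + 0, xmin = grid$xmin, ymax = grid$ymax, res = grid$res,
            crs = grid$crs)
}

#' Average a raster band under a mask
#'
#' Arithmetic mean of the valid (non-nodata) pixels where the mask is true.
#'
#' @param band single-band `et_raster`.
#' @param mask binary `et_raster` on the same grid.
#' @return list with `mean` and `n` (count of valid pixels averaged).
#' @export
average_over_mask <- function(band, mask) {
  stopifnot(inherits(band, "et_raster"), inherits(mask, "et_raster"))
  if (!all(dim(band$values)[1:2] == dim(mask$values)[1:2]))
    stop("band and mask grids differ")
  sel <- mask$values > 0 & !is.na(mask$values) & is.finite(band$values)
  if (!any(sel)) stop("no valid pixels under the mask")
  list(mean = mean(band$values[sel]), n = sum(sel))
}

#' Close the eddy-covariance energy balance by residual
#'
#' EC towers rarely close `Rn = H + LE + G`; mirroring the model - which
#' obtains latent heat as the balance residual - the whole imbalance is
#' attributed to LE: `LE_closed = Rn - G - H`.
#'
#' @param ec data frame with columns `rn`, `g`, `h_ec` (W/m2); other
#'   columns pass through.
#' @param method closure method; only `"residual_le"` is implemented
#'   (`"bowen"` and `"residual_h"` are recognized names that error with
#'   "not implemented").
#' @return the input tibble with a new column `le_closed`.
#' @export
close_ec_balance <- function(ec, method = "residual_le") {
  if (!identical(method, "residual_le"))
    stop("closure method '", method, "' not implemented")
  stopifnot(all(c("rn", "g", "h_ec") %in% names(ec)))
  dplyr::mutate(tibble::as_tibble(ec),
                le_closed = .data$rn - .data$g - .data$h_ec)
}

#' Validation statistics of modelled vs measured fluxes
#'
#' Root mean square error, its bias / scatter decomposition
#' (`RMSE^2 = bias^2 + RMSD^2`, with RMSD the root mean square deviation
#' about the mean difference), an ordinary least squares fit of modelled on
#' measured, and the Pearson correlation with its two-sided p value.
#'
#' @param pairs data frame with columns `modelled` and `measured` (W/m2),
#'   at least 3 rows.
#' @return an object of class `et_validation` with fields `rmse`, `rmsd`,
#'   `bias`, `slope`, `intercept`, `r`, `p_value`, `n`, `degenerate`
#'   (`TRUE` when a correlation is undefined, e.g. identical pairs), and
#'   the underlying `lm` fit (`NULL` when degenerate). Supports `tidy()`
#'   and `glance()`.
#' @export
validation_stats <- function(pairs) {
  stopifnot(all(c("modelled", "measured") %in% names(pairs)))
  pairs <- dplyr::filter(tibble::as_tibble(pairs),
                         is.finite(.data$modelled), is.finite(.data$measured))
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 modelled/measured pairs")
  diff <- pairs$modelled - pairs$measured
  bias <- mean(diff)
  rmse <- sqrt(mean(diff^2))
  rmsd <- sqrt(mean((diff - bias)^2))
  degenerate <- stats::sd(pairs$modelled) == 0 || stats::sd(pairs$measured) == 0
  if (degenerate) {
    fit <- NULL; slope <- NA_real_; intercept <- NA_real_
    r <- NA_real_; p <- NA_real_
  } else {
    fit <- stats::lm(modelled ~ measured, data = pairs)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    ct <- stats::cor.test(pairs$measured, pairs$modelled)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(rmse = rmse, rmsd = rmsd, bias = bias, slope = slope,
                 intercept = intercept, r = r, p_value = p, n = n,
                 degenerate = degenerate, fit = fit, pairs = pairs),
            class = "et_validation")
}

#' @export
print.et_validation <- function(x, ...) {
  cat(sprintf("<et_validation> n = %d: RMSE %.2f, RMSD %.2f, bias %+.2f W/m2\n",
              x$n, x$rmse, x$rmsd, x$bias))
  if (x$degenerate) cat("  correlation undefined (degenerate pairs)\n")
  else cat(sprintf("  modelled = %.3f * measured %+.2f;  r = %.3f, p = %.3g\n",
                   x$slope, x$intercept, x$r, x$p_value))
  invisible(x)
}

#' Match an EC record to a flight time
#'
#' Picks the half-hour record whose averaging interval contains the flight
#' midpoint.
#'
#' @param ec tibble with a `time` column giving the interval END (numeric
#'   seconds, the EC convention) and an `interval` length in seconds
#'   (default 1800).
#' @param flight_mid numeric flight midpoint time on the same scale.
#' @param interval averaging interval length, s.
#' @return the matching row (one-row tibble); error if none contains the
#'   midpoint.
#' @export
match_ec_record <- function(ec, flight_mid, interval = 1800) {
  sel <- ec$time - interval <= flight_mid & flight_mid < ec$time
  if (!any(sel)) stop("no EC interval contains the flight midpoint")
  ec[which(sel)[1], ]
}
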