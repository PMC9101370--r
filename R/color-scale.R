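#' 24-bit color key of an RGB triple
#'
#' Collapses an 8-bit (R, G, B) triple to a single integer key,
#' `(256^3 - 1) * R + (256^2 - 1) * G + 255 * B`. The key is injective over
#' all 8-bit triples (the blue term is below 256^2 - 1 and the green + blue
#' terms stay below 256^3 - 1), so colors can be compared and looked up by a
#' single number. Vectorised over equal-length channel vectors.
#'
#' @param r,g,b integer channel values in 0..255.
#' @return numeric vector of keys in 0 .. 255 * (256^3 + 256^2 + 254).
#' @examples
#' rgb_to_value(0, 0, 1)   # 255
#' rgb_to_value(0, 1, 0)   # 65535
#' rgb_to_value(1, 0, 0)   # 16777215
#' @export
rgb_to_value <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255) || any(c(r, g, b) %% 1 != 0))
    stop("channel values must be integers in 0..255")
  (256^3 - 1) * r + (256^2 - 1) * g + 255 * b
}

#' Construct or validate a thermal color scale
#'
#' An ordered palette of `N` distinct 8-bit colors: index 0 is the darkest
#' entry (minimum temperature), index `N - 1` the brightest (maximum
#' temperature). Thermal colorbars attached to camera snapshots carry 239
#' entries.
#'
#' @param colors integer matrix `N x 3` of RGB values in 0..255, ordered dark
#'   to bright.
#' @return an object of class `color_scale`: the color matrix plus the
#'   precomputed 24-bit key of every entry.
#' @seealso [make_color_scale()] for the synthetic default palette.
#' @export
color_scale <- function(colors) {
  colors <- as.matrix(colors)
  stopifnot(ncol(colors) == 3, nrow(colors) >= 2,
            all(colors >= 0 & colors <= 255), all(colors %% 1 == 0))
  keys <- rgb_to_value(colors[, 1], colors[, 2], colors[, 3])
  if (anyDuplicated(keys))
    stop("color scale entries must be distinct under the 24-bit key")
  structure(list(colors = colors, keys = keys, n_levels = nrow(colors)),
            class = "color_scale")
}

#' @export
print.color_scale <- function(x, ...) {
  cat(sprintf("<color_scale> %d levels, keys [%g, %g]\n",
              x$n_levels, min(x$keys), max(x$keys)))
  invisible(x)
}

#' Read or write a color scale as a PPM strip
#'
#' The colorbar travels with a flight as an `N x 1` (or `1 x N`) PPM image,
#' darkest entry first.
#'
#' @param path PPM file.
#' @param scale a `color_scale`.
#' @export
read_color_scale <- function(path) {
  img <- read_ppm(path)
  d <- dim(img)
  if (d[1] > 1 && d[2] > 1) stop("colorbar strip must be Nx1 or 1xN")
  n <- max(d[1], d[2])
  m <- matrix(img, n, 3)
  color_scale(m)
}

#' @rdname read_color_scale
#' @export
write_color_scale <- function(scale, path) {
  stopifnot(inherits(scale, "color_scale"))
  img <- array(scale$colors, dim = c(scale$n_levels, 1, 3))
  write_ppm(img, path)
}

#' Attribute colors to scale levels
#'
#' Looks each color up in the scale by its 24-bit key. Exact matches return
#' the level index (0-based). Colors absent from the palette - mosaicking
#' blends neighbouring colors - are attributed to the nearest key if its
#' absolute key distance is within `tolerance`, otherwise `NA` (nodata).
#'
#' @param colors integer matrix `n x 3` of RGB values.
#' @param scale a `color_scale`.
#' @param tolerance maximum absolute 24-bit key distance for a nearest-key
#'   match; 0 demands exact matches.
#' @return integer vector of 0-based level indices, `NA` where unattributable.
#' @export
attribute_color <- function(colors, scale, tolerance = 0) {
  stopifnot(inherits(scale, "color_scale"), tolerance >= 0)
  colors <- matrix(as.numeric(colors), ncol = 3)
  keys <- rgb_to_value(colors[, 1], colors[, 2], colors[, 3])
  ord <- order(scale$keys)
  skeys <- scale$keys[ord]
  # nearest sorted key via binary search on interval midpoints
  pos <- findInterval(keys, skeys)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(skeys))
  d_lo <- abs(keys - skeys[lo])
  d_hi <- abs(keys - skeys[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  idx <- ord[nearest] - 1L
  idx[dist > tolerance] <- NA_integer_
  as.integer(idx)
}

#' Map scale levels to temperature
#'
#' The temperature range of a snapshot is divided into `n_levels` values:
#' level 0 maps to `t_min`, level `n_levels - 1` to `t_max`, linearly in
#' between (step `(t_max - t_min) / (n_levels - 1)`).
#'
#' @param index 0-based level index (vectorised); `NA` passes through.
#' @param t_min,t_max snapshot temperature range, degrees C, `t_max > t_min`.
#' @param n_levels number of scale levels (239 for the camera colorbar).
#' @return temperature in degrees C.
#' @export
level_to_temperature <- function(index, t_min, t_max, n_levels = 239L) {
  stopifnot(t_max > t_min, n_levels >= 2)
  if (any(index < 0 | index > n_levels - 1, na.rm = TRUE))
    stop("level index out of range 0..", n_levels - 1)
  t_min + index * (t_max - t_min) / (n_levels - 1)
}

#' Inverse of [level_to_temperature()]: nearest level of a temperature
#'
#' Rounds half away from zero so quantization error is symmetric.
#' @inheritParams level_to_temperature
#' @param t temperature in degrees C within `[t_min, t_max]`.
#' @return 0-based level index.
#' @export
temperature_to_level <- function(t, t_min, t_max, n_levels = 239L) {
  stopifnot(t_max > t_min)
  if (any(t < t_min - 1e-9 | t > t_max + 1e-9, na.rm = TRUE))
    stop("temperature outside [t_min, t_max]")
  x <- (t - t_min) / (t_max - t_min) * (n_levels - 1)
  idx <- floor(x + 0.5)          # half-away-from-zero (x is non-negative here)
  pmin(pmax(idx, 0), n_levels - 1)
}
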