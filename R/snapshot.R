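#' Thermal snapshot
#'
#' A pseudo-colored thermal frame: an `H x W x 3` 8-bit image whose colors
#' index a [color_scale()], together with the frame's temperature range as
#' logged by the camera (isothermal minimum and maximum).
#'
#' @param pixels `H x W x 3` integer array, channel values 0..255.
#' @param t_min,t_max frame temperature range, degrees C, `t_max > t_min`.
#' @param scale a `color_scale` (the colorbar saved with the flight).
#' @param snapshot_id serial number of the frame.
#' @param timestamp trigger time, GPS seconds.
#' @return an object of class `thermal_snapshot`.
#' @export
thermal_snapshot <- function(pixels, t_min, t_max, scale,
                             snapshot_id = NA_integer_, timestamp = NA_real_) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            t_max > t_min, inherits(scale, "color_scale"))
  structure(list(pixels = pixels, t_min = t_min, t_max = t_max,
                 scale = scale, snapshot_id = snapshot_id,
                 timestamp = timestamp),
            class = "thermal_snapshot")
}

#' @export
print.thermal_snapshot <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<thermal_snapshot> #%s %d x %d px, range [%.2f, %.2f] C, %d-level scale\n",
              x$snapshot_id, d[1], d[2], x$t_min, x$t_max, x$scale$n_levels))
  invisible(x)
}

#' Decode a pseudo-colored snapshot to temperature
#'
#' Each pixel color is attributed to a colorbar level via its 24-bit key
#' ([attribute_color()]) and the level mapped linearly onto the frame's
#' temperature range ([level_to_temperature()]). Pixels whose color cannot
#' be attributed (off-palette beyond `tolerance`) become `NA`.
#'
#' @param s a [thermal_snapshot()].
#' @param tolerance key-distance tolerance passed to [attribute_color()];
#'   0 (exact) is appropriate for raw frames, a small positive value for
#'   imagery that has been resampled or blended.
#' @return numeric `H x W` matrix of temperatures, degrees C.
#' @export
decode_snapshot <- function(s, tolerance = 0) {
  stopifnot(inherits(s, "thermal_snapshot"))
  d <- dim(s$pixels)
  cols <- matrix(as.numeric(s$pixels), d[1] * d[2], 3)
  idx <- attribute_color(cols, s$scale, tolerance = tolerance)
  temp <- level_to_temperature(idx, s$t_min, s$t_max, s$scale$n_levels)
  matrix(temp, d[1], d[2])
}

#' Encode a temperature grid as a pseudo-colored snapshot
#'
#' Inverse of [decode_snapshot()]: temperatures are quantized to the nearest
#' colorbar level over `[t_min, t_max]` and painted with the scale colors.
#' Decoding the result reproduces the input within half a quantization step,
#' `(t_max - t_min) / (2 * (n_levels - 1))`.
#'
#' @param temp numeric `H x W` matrix of temperatures, all within
#'   `[t_min, t_max]`.
#' @inheritParams thermal_snapshot
#' @return a [thermal_snapshot()].
#' @export
encode_snapshot <- function(temp, t_min, t_max, scale,
                            snapshot_id = NA_integer_, timestamp = NA_real_) {
  stopifnot(is.matrix(temp), inherits(scale, "color_scale"))
  idx <- temperature_to_level(temp, t_min, t_max, scale$n_levels)
  px <- array(0L, dim = c(nrow(temp), ncol(temp), 3))
  for (ch in 1:3)
    px[, , ch] <- matrix(scale$colors[idx + 1L, ch], nrow(temp), ncol(temp))
  thermal_snapshot(px, t_min, t_max, scale, snapshot_id, timestamp)
}

#' Common temperature range of a flight
#'
#' Before mosaicking, every snapshot of a flight must share one temperature
#' scale; the common range is the elementwise envelope of the per-frame
#' ranges.
#'
#' @param events data frame with columns `t_min` and `t_max` (one row per
#'   snapshot), e.g. the output of [parse_event_log()].
#' @return named numeric vector `c(t_min = ..., t_max = ...)`.
#' @export
flight_common_range <- function(events) {
  if (is.list(events) && !is.data.frame(events))
    events <- dplyr::bind_rows(events)
  if (nrow(events) == 0) stop("no snapshot ranges supplied")
  stopifnot(all(c("t_min", "t_max") %in% names(events)))
  c(t_min = min(events$t_min), t_max = max(events$t_max))
}

#' Rescale a snapshot onto a common flight range
#'
#' Decodes each pixel under its own frame range, then re-encodes it against
#' the common range: the new color is the scale entry at
#' `round((T - t_common_min) / (t_common_max - t_common_min) * (N - 1))`.
#' Decoding the result reproduces the original temperature within half a
#' common-range quantization step.
#'
#' @param s a [thermal_snapshot()].
#' @param common numeric length-2, the common `(t_min, t_max)`; must enclose
#'   the snapshot's own range unless `clamp = TRUE`.
#' @param clamp clamp temperatures outside the common range to its ends
#'   (a message reports the count) instead of erroring.
#' @return a [thermal_snapshot()] with `t_min`/`t_max` set to the common
#'   range.
#' @export
rescale_snapshot <- function(s, common, clamp = FALSE) {
  stopifnot(inherits(s, "thermal_snapshot"), length(common) == 2)
  common <- as.numeric(common)
  if (common[2] <= common[1]) stop("invalid common range")
  encloses <- common[1] <= s$t_min + 1e-9 && common[2] >= s$t_max - 1e-9
  if (!encloses && !clamp)
    stop(sprintf("common range [%g, %g] does not enclose snapshot range [%g, %g]",
                 common[1], common[2], s$t_min, s$t_max))
  temp <- decode_snapshot(s)
  n_out <- sum(temp < common[1] | temp > common[2], na.rm = TRUE)
  if (n_out > 0) {
    message(n_out, " pixel(s) clamped to the common range")
    temp <- pmin(pmax(temp, common[1]), common[2])
  }
  encode_snapshot(temp, common[1], common[2], s$scale,
                  snapshot_id = s$snapshot_id, timestamp = s$timestamp)
}

#' Convert a pseudo-colored thermal mosaic to a temperature raster
#'
#' Applies the colorbar attribution to a georeferenced 3-band mosaic built
#' from rescaled snapshots. Mosaicking blends colors at seam lines, so the
#' attribution uses a nearest-key tolerance; pixels beyond it become nodata.
#' Georeferencing is carried over unchanged.
#'
#' @param mosaic 3-band byte `et_raster` (see [read_image_raster()]).
#' @param common the flight's common temperature range, length-2 numeric.
#' @param scale the flight [color_scale()].
#' @param tolerance nearest-key tolerance in 24-bit key units; the default
#'   `3 * 255` admits colors within one intensity step per channel.
#' @return a single-band `et_raster` of temperatures, degrees C.
#' @export
mosaic_to_temperature_raster <- function(mosaic, common, scale,
                                         tolerance = 3 * 255) {
  stopifnot(inherits(mosaic, "et_raster"), n_bands(mosaic) == 3L,
            length(common) == 2, common[2] > common[1])
  d <- dim(mosaic$values)
  cols <- matrix(as.numeric(mosaic$values), d[1] * d[2], 3)
  idx <- attribute_color(cols, scale, tolerance = tolerance)
  temp <- level_to_temperature(idx, common[1], common[2], scale$n_levels)
  et_raster(matrix(temp, d[1], d[2]), xmin = mosaic$xmin, ymax = mosaic$ymax,
            res = mosaic$res, crs = mosaic$crs)
}

#' Read and write snapshots as PPM files
#'
#' A snapshot on disk is its PPM image; the temperature range and serial
#' live in the flight event log, the colorbar in the flight's strip file.
#'
#' @inheritParams thermal_snapshot
#' @param path PPM path.
#' @export
read_snapshot <- function(path, t_min, t_max, scale,
                          snapshot_id = NA_integer_, timestamp = NA_real_) {
  thermal_snapshot(read_ppm(path), t_min, t_max, scale, snapshot_id, timestamp)
}

#' @rdname read_snapshot
#' @param s a [thermal_snapshot()].
#' @export
write_snapshot <- function(s, path) {
  stopifnot(inherits(s, "thermal_snapshot"))
  write_ppm(s$pixels, path)
}
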