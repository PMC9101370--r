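#' Lightweight georeferenced raster
#'
#' In-memory raster used throughout the pipeline: a numeric matrix (single
#' band) or a three-dimensional array (rows x cols x bands) plus an axis-
#' aligned affine georeferencing (top-left corner, square pixels, north-up).
#' Row 1 is the northernmost row. Coordinates are in the units of `crs`,
#' normally metres of a local projected frame (see [local_frame()]).
#'
#' @param values numeric matrix or rows x cols x bands array. `NA` is nodata.
#' @param xmin x coordinate of the west edge (left edge of column 1).
#' @param ymax y coordinate of the north edge (top edge of row 1).
#' @param res pixel size (same in x and y), in CRS units per pixel.
#' @param crs free-form CRS label; rasters entering one computation must agree.
#' @return an object of class `et_raster`.
#' @examples
#' r <- et_raster(matrix(1:12, 3, 4), xmin = 0, ymax = 3, res = 1)
#' raster_extent(r)
#' @export
et_raster <- function(values, xmin = 0, ymax = NULL, res = 1, crs = "local") {
  if (is.vector(values)) values <- matrix(values, 1)
  stopifnot(is.numeric(values) || is.logical(values),
            length(dim(values)) %in% c(2L, 3L), res > 0)
  if (is.null(ymax)) ymax <- nrow(values) * res
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         res = as.numeric(res), crs = crs),
    class = "et_raster"
  )
}

#' @export
print.et_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<et_raster> %d x %d px%s, res %g, x [%g, %g], y [%g, %g], crs '%s'\n",
              d[1], d[2], if (length(d) == 3) sprintf(" x %d bands", d[3]) else "",
              x$res, x$xmin, x$xmin + d[2] * x$res,
              x$ymax - d[1] * x$res, x$ymax, x$crs))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                             sum(is.na(x$values))))
  invisible(x)
}

#' @rdname et_raster
#' @param r an `et_raster`.
#' @export
raster_extent <- function(r) {
  d <- dim(r$values)
  c(xmin = r$xmin, xmax = r$xmin + d[2] * r$res,
    ymin = r$ymax - d[1] * r$res, ymax = r$ymax)
}

#' @rdname et_raster
#' @export
n_bands <- function(r) if (length(dim(r$values)) == 3) dim(r$values)[3] else 1L

# pixel-centre coordinates of every cell, row-major
raster_xy <- function(r) {
  d <- dim(r$values)
  x <- r$xmin + (seq_len(d[2]) - 0.5) * r$res
  y <- r$ymax - (seq_len(d[1]) - 0.5) * r$res
  list(x = x, y = y)
}

# band accessor that always returns a matrix
raster_band <- function(r, band = 1L) {
  if (length(dim(r$values)) == 3) r$values[, , band] else r$values
}

same_grid <- function(a, b, tol = 1e-9) {
  da <- dim(a$values)[1:2]; db <- dim(b$values)[1:2]
  all(da == db) && abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$res - b$res) < tol && identical(a$crs, b$crs)
}

#' Tidy raster to a tibble of pixel centres
#'
#' One row per pixel (and band), columns `x`, `y`, `band`, `value`. The
#' long format plugs straight into ggplot2 / dplyr.
#'
#' @param x an `et_raster`.
#' @param ... unused.
#' @return a tibble.
#' @export
as_tibble.et_raster <- function(x, ...) {
  xy <- raster_xy(x)
  nb <- n_bands(x)
  purrr::map_dfr(seq_len(nb), function(b) {
    m <- raster_band(x, b)
    tibble::tibble(
      x = rep(xy$x, each = nrow(m)),
      y = rep(xy$y, times = ncol(m)),
      band = b,
      value = as.vector(m)
    )
  })
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text georeferenced grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by row-major values,
#' north row first). Used for all float rasters (temperature, LAI, fluxes).
#'
#' @param r single-band `et_raster`.
#' @param path file path (conventionally `.asc`).
#' @param crs CRS label to attach on read (the format itself carries none).
#' @param digits significant digits written.
#' @return `read_ascii_grid` returns an `et_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 9) {
  stopifnot(inherits(r, "et_raster"), n_bands(r) == 1L)
  d <- dim(r$values)
  nodata <- -9999
  v <- r$values
  v[!is.finite(v)] <- nodata
  header <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymax - d[1] * r$res),
    sprintf("cellsize %.10g", r$res),
    sprintf("NODATA_value %d", nodata)
  )
  rows <- apply(v, 1, function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, crs = "local") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid payload size mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  et_raster(m, xmin = hdr$xllcorner,
            ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
            res = hdr$cellsize, crs = crs)
}

#' Read and write byte imagery as TIFF + world file
#'
#' Multi-band 8-bit imagery (RGB orthomosaics, pseudo-colored thermal
#' mosaics) is stored as a baseline TIFF with the georeferencing in an ESRI
#' world file (same path, `.tfw` extension). Values are 8-bit channel
#' intensities 0..255.
#'
#' @param r `et_raster` with integer values in 0..255.
#' @param path TIFF path; the world file is written alongside.
#' @param crs CRS label attached on read.
#' @return `read_image_raster` returns an `et_raster`; the writer returns
#'   `path` invisibly.
#' @export
write_image_raster <- function(r, path) {
  stopifnot(inherits(r, "et_raster"))
  v <- r$values
  stopifnot(all(v >= 0 & v <= 255, na.rm = TRUE))
  tiff::writeTIFF(v / 255, path, bits.per.sample = 8L)
  # world file: x pixel size, 0, 0, -y pixel size, centre of upper-left pixel
  wf <- c(r$res, 0, 0, -r$res, r$xmin + r$res / 2, r$ymax - r$res / 2)
  writeLines(sprintf("%.10g", wf), world_file_path(path))
  invisible(path)
}

#' @rdname write_image_raster
#' @export
read_image_raster <- function(path, crs = "local") {
  v <- tiff::readTIFF(path)
  v <- round(v * 255)
  wfp <- world_file_path(path)
  if (!file.exists(wfp))
    stop("missing georeferencing: no world file ", wfp)
  wf <- as.numeric(readLines(wfp))
  if (length(wf) != 6 || any(!is.finite(wf)))
    stop("malformed world file ", wfp)
  res <- wf[1]
  et_raster(v, xmin = wf[5] - res / 2, ymax = wf[6] + res / 2,
            res = res, crs = crs)
}

world_file_path <- function(path) sub("\\.[^.]+$", ".tfw", path)

#' Resample a raster onto a target grid
#'
#' Continuous fields are aggregated by the mean of the source pixels whose
#' centres fall in each target cell (`method = "mean"`); categorical rasters
#' take the source pixel containing the target-cell centre
#' (`method = "nearest"`). Nodata-aware: `NA` source pixels are dropped from
#' means; target cells with no contributing source pixel become `NA`.
#'
#' @param r source single-band `et_raster`.
#' @param target `et_raster` (values ignored) defining the output grid.
#' @param method `"mean"` or `"nearest"`.
#' @return an `et_raster` on the target grid.
#' @export
resample_to_grid <- function(r, target, method = c("mean", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(r, "et_raster"), inherits(target, "et_raster"),
            n_bands(r) == 1L)
  if (!identical(r$crs, target$crs))
    stop("CRS mismatch: '", r$crs, "' vs '", target$crs, "'")
  es <- raster_extent(r); et <- raster_extent(target)
  if (es["xmin"] >= et["xmax"] || es["xmax"] <= et["xmin"] ||
      es["ymin"] >= et["ymax"] || es["ymax"] <= et["ymin"])
    stop("source and target extents are disjoint")
  dt <- dim(target$values)[1:2]
  out <- matrix(NA_real_, dt[1], dt[2])
  if (method == "nearest") {
    xy <- raster_xy(target)
    col_s <- floor((xy$x - r$xmin) / r$res) + 1L
    row_s <- floor((r$ymax - xy$y) / r$res) + 1L
    ok_c <- col_s >= 1L & col_s <= ncol(r$values)
    ok_r <- row_s >= 1L & row_s <= nrow(r$values)
    for (i in which(ok_r)) {
      out[i, ok_c] <- r$values[row_s[i], col_s[ok_c]]
    }
  } else {
    xy <- raster_xy(r)
    col_t <- floor((xy$x - target$xmin) / target$res) + 1L
    row_t <- floor((target$ymax - xy$y) / target$res) + 1L
    ok_c <- col_t >= 1L & col_t <= dt[2]
    ok_r <- row_t >= 1L & row_t <= dt[1]
    idx <- expand.grid(sr = which(ok_r), sc = which(ok_c))
    cell <- (col_t[idx$sc] - 1L) * dt[1] + row_t[idx$sr]
    val <- r$values[cbind(idx$sr, idx$sc)]
    keep <- !is.na(val)
    sums <- rowsum(val[keep], cell[keep])
    cnts <- rowsum(rep(1, sum(keep)), cell[keep])
    out[as.integer(rownames(sums))] <- sums / cnts
  }
  et_raster(out, xmin = target$xmin, ymax = target$ymax,
            res = target$res, crs = target$crs)
}

#' Local metric frame helpers
#'
#' The pipeline works in a local east/north frame in metres, anchored at a
#' reference longitude/latitude. The conversion is an equirectangular
#' projection about the anchor - accurate to well under a decimetre over the
#' few-hundred-metre extents of a UAV flight.
#'
#' @param lon,lat coordinates in decimal degrees (WGS-84).
#' @param anchor `c(lon, lat)` of the frame origin.
#' @return `lonlat_to_local` returns a two-column matrix of x (east) and
#'   y (north) metres; `local_to_lonlat` the inverse.
#' @export
lonlat_to_local <- function(lon, lat, anchor) {
  R <- 6378137
  x <- (lon - anchor[1]) * pi / 180 * R * cos(anchor[2] * pi / 180)
  y <- (lat - anchor[2]) * pi / 180 * R
  cbind(x = x, y = y)
}

#' @rdname lonlat_to_local
#' @param x,y local coordinates in metres.
#' @export
local_to_lonlat <- function(x, y, anchor) {
  R <- 6378137
  lon <- anchor[1] + x / (R * cos(anchor[2] * pi / 180)) * 180 / pi
  lat <- anchor[2] + y / R * 180 / pi
  cbind(lon = lon, lat = lat)
}
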