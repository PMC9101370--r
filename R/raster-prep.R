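#' Visible-band vegetation indices
#'
#' Computes a vegetation index from a 3-band RGB raster. Two ratio indices
#' built from the visible bands are supported:
#' \describe{
#'   \item{VI}{green-red ratio index, `(G - R) / (G + R)`}
#'   \item{VARI}{visible atmospherically resistant index,
#'     `(G - R) / (G + R - B)`}
#' }
#' Byte imagery is normalized to `[0, 1]` (division by 255) before the
#' ratios; being ratios, both indices are invariant to uniform channel
#' scaling. Zero-denominator pixels become `NA`.
#'
#' @param rgb 3-band `et_raster` (byte 0..255 or float already in `[0, 1]`).
#' @param kind `"VARI"` or `"VI"`.
#' @return single-band `et_raster` of index values.
#' @export
compute_index <- function(rgb, kind = c("VARI", "VI")) {
  kind <- match.arg(kind)
  stopifnot(inherits(rgb, "et_raster"))
  if (n_bands(rgb) != 3L) stop("index computation needs a 3-band raster")
  v <- rgb$values
  if (max(v, na.rm = TRUE) > 1) v <- v / 255
  R <- v[, , 1]; G <- v[, , 2]; B <- v[, , 3]
  den <- if (kind == "VARI") G + R - B else G + R
  idx <- (G - R) / den
  idx[abs(den) < 1e-12] <- NA_real_
  et_raster(idx, xmin = rgb$xmin, ymax = rgb$ymax, res = rgb$res,
            crs = rgb$crs)
}

#' Regress ground LAI on a vegetation index
#'
#' Ordinary least squares `LAI = slope * index + intercept`, fitted
#' separately against VI and VARI; the index kind with the higher R-squared
#' is kept (ties go to VARI). Ground truth comes from ceptometer point
#' measurements co-located with index samples from the RGB mosaic.
#'
#' @param points data frame with columns `lai`, `vi`, `vari` (one row per
#'   ceptometer point). A column of all-`NA` drops that kind from the race.
#' @return an object of class `lai_model` with fields `kind`, `slope`,
#'   `intercept`, `r_squared`, `n_points` and the underlying `lm` fit.
#'   Supports `tidy()` and `glance()`.
#' @export
fit_lai_model <- function(points) {
  stopifnot(all(c("lai", "vi", "vari") %in% names(points)))
  points <- dplyr::filter(points, !is.na(.data$lai))
  if (nrow(points) < 2) stop("need at least 2 LAI points")
  fit_one <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0) return(NULL)
    stats::lm(lai ~ x, data = data.frame(lai = points$lai, x = x))
  }
  fits <- list(VI = fit_one(points$vi), VARI = fit_one(points$vari))
  r2 <- vapply(fits, function(f) {
    if (is.null(f)) return(-Inf)
    suppressWarnings(summary(f)$r.squared)   # exact fits warn harmlessly
  }, numeric(1))
  if (all(!is.finite(r2)))
    stop("degenerate inputs: both index columns constant or missing")
  kind <- if (r2["VARI"] >= r2["VI"]) "VARI" else "VI"
  f <- fits[[kind]]
  structure(list(kind = kind,
                 slope = unname(stats::coef(f)[2]),
                 intercept = unname(stats::coef(f)[1]),
                 r_squared = unname(r2[kind]),
                 n_points = nrow(points),
                 fit = f),
            class = "lai_model")
}

#' @export
print.lai_model <- function(x, ...) {
  cat(sprintf("<lai_model> LAI = %.4g * %s %+.4g  (R^2 = %.3f, n = %d)\n",
              x$slope, x$kind, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict an LAI raster from a fitted index regression
#'
#' Applies `slope * index + intercept` per pixel and clamps the result below
#' at zero (a leaf area index cannot be negative). Nodata propagates.
#'
#' @param model a [fit_lai_model()] result.
#' @param index single-band `et_raster` of the model's index kind.
#' @param kind index kind of `index`; must equal `model$kind`.
#' @return single-band `et_raster` of LAI (m2/m2).
#' @export
lai_map <- function(model, index, kind = model$kind) {
  stopifnot(inherits(model, "lai_model"), inherits(index, "et_raster"))
  if (!identical(kind, model$kind))
    stop("index kind '", kind, "' does not match the fitted model ('",
         model$kind, "')")
  v <- pmax(model$slope * index$values + model$intercept, 0)
  et_raster(v, xmin = index$xmin, ymax = index$ymax, res = index$res,
            crs = index$crs)
}

#' Classify green vegetation from RGB
#'
#' A pixel is green when its VARI exceeds `threshold`. With
#' `threshold = "otsu"` the cut is placed automatically between the modes of
#' the VARI histogram (Otsu's criterion), for scenes where the default does
#' not separate soil from canopy.
#'
#' @param rgb 3-band `et_raster`.
#' @param threshold numeric VARI threshold (default 0.05) or `"otsu"`.
#' @return single-band logical-valued `et_raster` (1 green, 0 not, `NA`
#'   where the index is undefined).
#' @export
green_mask <- function(rgb, threshold = 0.05) {
  vari <- compute_index(rgb, "VARI")
  v <- vari$values
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(v[is.finite(v)])
  m <- v > threshold
  et_raster(m + 0, xmin = rgb$xmin, ymax = rgb$ymax, res = rgb$res,
            crs = rgb$crs)
}

# Otsu's between-class variance maximization on a 256-bin histogram
otsu_threshold <- function(x) {
  if (length(x) == 0) return(0.05)
  br <- seq(min(x), max(x), length.out = 257)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (br[k] + br[k + 1]) / 2
}

#' Aggregate a binary mask to a cover-fraction raster
#'
#' Fraction of true sub-pixels of a fine-resolution mask per cell of the
#' (coarser) target grid - the green fraction or fractional cover at the
#' thermal grid resolution. The site mode applies the standing assumptions:
#' on grassland the cover is total (`f_c = 1`) and the fraction is the green
#' fraction `f_g`; on cropland all vegetation is green (`f_g = 1`) and the
#' fraction is the fractional cover `f_c`.
#'
#' @param mask binary `et_raster` (from [green_mask()]), resolution finer
#'   than or equal to the target.
#' @param target `et_raster` defining the output grid.
#' @param site `"grassland"` or `"cropland"` (see Details), or `"none"` to
#'   return just the fraction.
#' @return for `site = "none"` a single fraction raster in `[0, 1]`;
#'   otherwise a list with elements `f_c` and `f_g` on the target grid.
#' @export
fraction_raster <- function(mask, target, site = c("none", "grassland", "cropland")) {
  site <- match.arg(site)
  stopifnot(inherits(mask, "et_raster"), inherits(target, "et_raster"))
  if (mask$res > target$res + 1e-9)
    stop("mask resolution must be finer than or equal to the target grid")
  frac <- resample_to_grid(mask, target, method = "mean")
  frac$values <- pmin(pmax(frac$values, 0), 1)
  if (site == "none") return(frac)
  ones <- et_raster(matrix(1, nrow(frac$values), ncol(frac$values)),
                    xmin = frac$xmin, ymax = frac$ymax, res = frac$res,
                    crs = frac$crs)
  ones$values[is.na(frac$values)] <- NA_real_
  if (site == "grassland") list(f_c = ones, f_g = frac)
  else list(f_c = frac, f_g = ones)
}

#' Sample a raster at point locations
#'
#' Mean over a square window of pixels centred on each point - the way
#' index values are extracted at ceptometer / marker locations.
#'
#' @param r single-band `et_raster`.
#' @param x,y point coordinates in the raster CRS.
#' @param window odd window edge length in pixels (default 5).
#' @return numeric vector of window means (`NA` outside the raster).
#' @export
sample_raster <- function(r, x, y, window = 5) {
  stopifnot(inherits(r, "et_raster"), window %% 2 == 1)
  half <- (window - 1) / 2
  d <- dim(r$values)[1:2]
  col0 <- floor((x - r$xmin) / r$res) + 1L
  row0 <- floor((r$ymax - y) / r$res) + 1L
  vapply(seq_along(x), function(i) {
    rows <- max(1, row0[i] - half):min(d[1], row0[i] + half)
    cols <- max(1, col0[i] - half):min(d[2], col0[i] + half)
    if (row0[i] < 1 || row0[i] > d[1] || col0[i] < 1 || col0[i] > d[2])
      return(NA_real_)
    mean(r$values[rows, cols], na.rm = TRUE)
  }, numeric(1))
}

#' Assemble co-registered TSEB surface inputs
#'
#' Bundles the four per-pixel model inputs - radiometric temperature, LAI,
#' fractional cover and green fraction - after checking that they share one
#' grid. LAI, f_c and f_g are resampled (mean) onto the thermal grid first
#' when their grids differ.
#'
#' @param t_rad temperature `et_raster` (degrees C), the reference grid.
#' @param lai,f_c,f_g `et_raster`s.
#' @return an object of class `surface_inputs` (list of the four rasters).
#' @export
surface_inputs <- function(t_rad, lai, f_c, f_g) {
  al <- list(t_rad = t_rad, lai = lai, f_c = f_c, f_g = f_g)
  stopifnot(all(vapply(al, inherits, logical(1), "et_raster")))
  for (nm in c("lai", "f_c", "f_g"))
    if (!same_grid(al[[nm]], t_rad))
      al[[nm]] <- resample_to_grid(al[[nm]], t_rad, method = "mean")
  rng <- function(r, lo, hi, nm) {
    v <- r$values[is.finite(r$values)]
    if (length(v) && (min(v) < lo - 1e-9 || max(v) > hi + 1e-9))
      stop(nm, " outside [", lo, ", ", hi, "]")
  }
  rng(al$f_c, 0, 1, "f_c"); rng(al$f_g, 0, 1, "f_g")
  rng(al$lai, 0, Inf, "lai")
  structure(al, class = "surface_inputs")
}

#' @export
print.surface_inputs <- function(x, ...) {
  d <- dim(x$t_rad$values)
  cat(sprintf("<surface_inputs> %d x %d px at %g m: t_rad, lai, f_c, f_g\n",
              d[1], d[2], x$t_rad$res))
  invisible(x)
}
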