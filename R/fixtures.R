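#' Synthetic colorbar
#'
#' Default palette for synthetic flights: a monotone grayscale ramp of `n`
#' distinct levels (strictly increasing 24-bit key), darkest first - the
#' ordering and injectivity the codec relies on, without committing to any
#' proprietary camera palette. `mode = "scrambled"` draws `n` distinct
#' random colors instead (keys distinct but unordered), to exercise
#' order-independence of the key lookup.
#'
#' @param n number of levels (2..256^3), default 239 as on the camera
#'   colorbar.
#' @param mode `"gray"` or `"scrambled"`.
#' @param seed RNG seed for `"scrambled"`.
#' @return a [color_scale()].
#' @export
make_color_scale <- function(n = 239L, mode = c("gray", "scrambled"), seed = 1L) {
  mode <- match.arg(mode)
  if (n < 2 || n > 256^3) stop("n must be in 2..256^3")
  if (mode == "gray") {
    if (n > 256) stop("grayscale mode supports at most 256 levels")
    v <- round((seq_len(n) - 1) * 255 / (n - 1))
    return(color_scale(cbind(v, v, v)))
  }
  withr::with_seed(seed, {
    keys <- sample(0:(256^3 - 1), n)
  })
  r <- keys %/% 65536; g <- (keys %/% 256) %% 256; b <- keys %% 256
  color_scale(cbind(r, g, b))
}

#' Synthetic scene specification
#'
#' Parametric description of a study scene: extent and resolution, smooth
#' random fields for leaf area index, cover and soil warming, the site mode
#' and the micrometeorological state. All generated fields are pure
#' functions of `(spec, seed)`.
#'
#' Defaults emulate a mid-season grassland flight: ~60 m scene at 8 cm
#' would be 750 px across; the default keeps the same physical extent at a
#' coarser working resolution so tests stay fast (the generator is
#' resolution-agnostic).
#'
#' @param extent scene edge lengths `c(x, y)` in metres.
#' @param res pixel size in metres.
#' @param site `"grassland"` or `"cropland"`.
#' @param lai_base,lai_amp mean and smooth-field amplitude of LAI (m2/m2).
#' @param ts_offset_base,ts_offset_amp soil warming above air temperature,
#'   degrees C (base + smooth field).
#' @param fg_base,fg_amp green fraction field (grassland mode).
#' @param fc_base,fc_amp fractional cover field (cropland mode).
#' @param met a [micromet()] record.
#' @param anchor `c(lon, lat)` anchoring the local frame.
#' @param seed RNG seed for the smooth fields.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(extent = c(60, 60), res = 1, site = "grassland",
                       lai_base = 1.5, lai_amp = 0.8,
                       ts_offset_base = 5, ts_offset_amp = 3,
                       fg_base = 0.8, fg_amp = 0.15,
                       fc_base = 0.7, fc_amp = 0.2,
                       met = micromet(t_air = 25, wind = 2.5, pressure = 1010,
                                      e_a = 15, s_dn = 800, z_u = 3, z_t = 3,
                                      h_c = 0.3),
                       anchor = c(19.6, 46.69), seed = 1L) {
  site <- match.arg(site, c("grassland", "cropland"))
  structure(list(extent = extent, res = res, site = site,
                 lai_base = lai_base, lai_amp = lai_amp,
                 ts_offset_base = ts_offset_base, ts_offset_amp = ts_offset_amp,
                 fg_base = fg_base, fg_amp = fg_amp,
                 fc_base = fc_base, fc_amp = fc_amp,
                 met = met, anchor = anchor, seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth random field in [-1, 1]: blurred white noise, fixed seed
smooth_field <- function(nr, nc, seed, smoothing = 7) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
  })
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * smoothing + 1))
  k <- k / sum(k)
  # separable blur with replicated edges
  pad_blur <- function(m) {
    mp <- m[c(rep(1, smoothing), seq_len(nrow(m)), rep(nrow(m), smoothing)), ]
    s <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    s[(smoothing + 1):(smoothing + nrow(m)), , drop = FALSE]
  }
  z <- pad_blur(z)
  z <- t(pad_blur(t(z)))
  z / max(abs(z))
}

scene_dims <- function(scene) {
  c(nr = round(scene$extent[2] / scene$res),
    nc = round(scene$extent[1] / scene$res))
}

scene_raster <- function(scene, values) {
  et_raster(values, xmin = 0, ymax = scene$extent[2], res = scene$res,
            crs = "local")
}

#' Generate the surface fields of a scene
#'
#' @param scene a [scene_spec()].
#' @return list of `et_raster`s: `lai`, `f_c`, `f_g`, `ts_offset` (soil
#'   temperature excess over air, degrees C).
#' @export
scene_fields <- function(scene) {
  d <- scene_dims(scene)
  lai <- pmax(scene$lai_base +
                scene$lai_amp * smooth_field(d[1], d[2], scene$seed), 0)
  tso <- pmax(scene$ts_offset_base +
                scene$ts_offset_amp * smooth_field(d[1], d[2], scene$seed + 1), 0.5)
  if (scene$site == "grassland") {
    f_c <- matrix(1, d[1], d[2])
    f_g <- pmin(pmax(scene$fg_base +
                       scene$fg_amp * smooth_field(d[1], d[2], scene$seed + 2),
                     0.05), 1)
  } else {
    f_c <- pmin(pmax(scene$fc_base +
                       scene$fc_amp * smooth_field(d[1], d[2], scene$seed + 2),
                     0.05), 1)
    f_g <- matrix(1, d[1], d[2])
  }
  list(lai = scene_raster(scene, lai), f_c = scene_raster(scene, f_c),
       f_g = scene_raster(scene, f_g), ts_offset = scene_raster(scene, tso))
}

#' Forward-model a scene into surface inputs and flux truth
#'
#' Builds a radiometric temperature field that is exactly consistent with
#' the two-source energy balance at the given parameters: per pixel the
#' soil temperature is prescribed (air temperature + the scene's soil
#' warming field), the canopy temperature is solved from the
#' Priestley-Taylor canopy closure through the series resistance network
#' (a closed-form linear solve at fixed resistances, iterated with the
#' radiation and stability terms to a fixed point), and the radiometric
#' temperature follows from the view-fraction decomposition. The emitted
#' fluxes therefore satisfy `Rn = H + LE + G` exactly and are recoverable
#' by [run_tseb()].
#'
#' @param scene a [scene_spec()].
#' @param params a [tseb_parameters()]; scenes that drive the soil latent
#'   heat negative at these parameters are rejected with an error (no
#'   physical solution under the moist-soil construction).
#' @return list with `inputs` (a [surface_inputs()]) and `truth` (a
#'   `flux_raster` of the known fluxes, all pixels flagged converged).
#' @export
forward_fluxes <- function(scene, params = tseb_parameters()) {
  fl <- scene_fields(scene)
  met <- scene$met
  d <- dim(fl$lai$values)
  psy <- psychrometrics(met$t_air, met$pressure, met$e_a)
  rho_cp <- psy$rho_air * psy$c_p
  pt_frac_base <- psy$delta / (psy$delta + psy$gamma)
  t_ak <- met$t_air + 273.15

  n <- prod(d)
  t_rad <- matrix(NA_real_, d[1], d[2])
  bands <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    lai <- fl$lai$values[i]; f_c <- fl$f_c$values[i]; f_g <- fl$f_g$values[i]
    t_sk <- t_ak + fl$ts_offset$values[i]
    f_th <- f_theta_nadir(lai, f_c, params$f_theta_max)
    pt_frac <- f_g * pt_frac_base
    t_rk <- t_sk                       # starting guess
    inv_l <- 0
    for (it in 1:60) {
      L <- if (inv_l == 0) Inf else 1 / inv_l
      res <- resistances(met$wind, met$z_u, met$z_t, met$h_c, lai, L, params)
      rad <- partition_radiation(met$s_dn, met$t_air, t_rk - 273.15, met$e_a,
                                 lai, f_c, params)
      target <- rad$rn_canopy * (1 - params$alpha_pt * pt_frac)
      s_inv <- 1 / res$r_a + 1 / res$r_x + 1 / res$r_s
      a_term <- t_ak / res$r_a + t_sk / res$r_s
      # rho_cp (T_c - T_ac)/r_x = target, T_ac = (a + T_c/r_x)/s  (linear)
      t_ck <- (target * res$r_x / rho_cp + a_term / s_inv) /
        (1 - 1 / (res$r_x * s_inv))
      t_rk_new <- (f_th * t_ck^4 + (1 - f_th) * t_sk^4)^0.25
      t_ac <- (a_term + t_ck / res$r_x) / s_inv
      h_c <- rho_cp * (t_ck - t_ac) / res$r_x
      h_s <- rho_cp * (t_sk - t_ac) / res$r_s
      h_tot <- h_c + h_s
      inv_l_new <- if (abs(h_tot) < 1e-3) 0 else
        -(.von_karman * .gravity * h_tot) / (rho_cp * res$u_star^3 * t_ak)
      conv <- abs(t_rk_new - t_rk) < 1e-6 &&
        abs(inv_l_new - inv_l) <= 1e-4 * max(abs(inv_l), 1e-4)
      t_rk <- t_rk_new
      inv_l <- 0.5 * inv_l + 0.5 * inv_l_new
      if (conv) break
    }
    rad <- partition_radiation(met$s_dn, met$t_air, t_rk - 273.15, met$e_a,
                               lai, f_c, params)
    g_flux <- params$c_g * rad$rn_soil
    le_c <- rad$rn_canopy - h_c
    le_s <- rad$rn_soil - g_flux - h_s
    if (le_s < 0)
      stop(sprintf("no physical solution at pixel %d: soil latent heat %.1f W/m2 < 0 (scene too hot/dry for alpha_pt = %g)",
                   i, le_s, params$alpha_pt))
    t_rad[i] <- t_rk - 273.15
    bands[i, ] <- c(rad$rn, h_c + h_s, le_c + le_s, g_flux, 1)
  }
  inputs <- surface_inputs(scene_raster(scene, t_rad), fl$lai, fl$f_c, fl$f_g)
  truth <- et_raster(array(bands, dim = c(d[1], d[2], 5)),
                     xmin = 0, ymax = scene$extent[2], res = scene$res,
                     crs = "local")
  truth$band_names <- c("rn", "h", "le", "g", "converged")
  class(truth) <- c("flux_raster", class(truth))
  list(inputs = inputs, truth = truth)
}

#' Simulate a complete flight over a scene
#'
#' Flies a serpentine pattern over the scene, triggering a thermal snapshot
#' every `snapshot_interval` seconds (the 1.9 s camera-loop cadence) while
#' the GNSS rover records a 5 Hz track. Emits, under `out_dir`, everything
#' the pipeline consumes: one PPM per snapshot, the flight colorbar strip,
#' the camera event log (id, frame min/max temperature, NMEA GGA sentence
#' in UTC), an RTKLIB-style `.pos` track in GPS time, plus an in-memory
#' truth table of the exact camera positions for verification.
#'
#' @param scene a [scene_spec()].
#' @param out_dir output directory (created).
#' @param duration flight length, s.
#' @param snapshot_interval camera trigger cadence, s.
#' @param track_rate GNSS rate, Hz.
#' @param t_rad temperature raster to image; defaults to the scene's
#'   forward-modelled radiometric temperature.
#' @param scale a [color_scale()]; default [make_color_scale()].
#' @param snapshot_px snapshot footprint `c(rows, cols)` in scene pixels.
#' @param start_time flight start, GPS seconds since the epoch of `date`.
#' @param date flight date (`YYYY-MM-DD`).
#' @param leap_seconds GPST - UTC offset written into the NMEA sentences.
#' @return list with `events_file`, `pos_file`, `scale_file`,
#'   `snapshot_files`, `truth` (tibble: snapshot_id, time, x, y, lon, lat),
#'   `common_range`.
#' @export
simulate_flight <- function(scene, out_dir, duration = 60,
                            snapshot_interval = 1.9, track_rate = 5,
                            t_rad = NULL, scale = make_color_scale(),
                            snapshot_px = c(24, 32),
                            start_time = 36000, date = "2020-06-20",
                            leap_seconds = 18) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(t_rad)) t_rad <- forward_fluxes(scene)$inputs$t_rad
  d <- dim(t_rad$values)
  day0 <- as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC"))

  ev_t <- seq(0, duration, by = snapshot_interval)
  n_ev <- length(ev_t)
  path <- serpentine_path(scene$extent, n_ev)
  # densify the path for the 5 Hz track (same span as the events)
  tr_t <- seq(0, duration, by = 1 / track_rate)
  tr_xy <- path_at(path, tr_t / duration)
  ev_xy <- path_at(path, ev_t / duration)
  ev_ll <- local_to_lonlat(ev_xy[, 1], ev_xy[, 2], scene$anchor)
  tr_ll <- local_to_lonlat(tr_xy[, 1], tr_xy[, 2], scene$anchor)

  # snapshots: crops of the temperature field around the ground position
  hr <- snapshot_px[1] %/% 2; hc <- snapshot_px[2] %/% 2
  snap_files <- character(n_ev)
  log_lines <- character(n_ev)
  ranges <- matrix(NA_real_, n_ev, 2)
  for (k in seq_len(n_ev)) {
    col0 <- min(max(floor((ev_xy[k, 1] - t_rad$xmin) / t_rad$res) + 1L,
                    hc + 1L), d[2] - hc)
    row0 <- min(max(floor((t_rad$ymax - ev_xy[k, 2]) / t_rad$res) + 1L,
                    hr + 1L), d[1] - hr)
    crop <- t_rad$values[(row0 - hr):(row0 + hr - 1),
                         (col0 - hc):(col0 + hc - 1)]
    tmin <- floor(min(crop) * 10) / 10
    tmax <- ceiling(max(crop) * 10) / 10
    if (tmax <= tmin) tmax <- tmin + 0.1
    ranges[k, ] <- c(tmin, tmax)
    s <- encode_snapshot(crop, tmin, tmax, scale, snapshot_id = k,
                         timestamp = day0 + start_time + ev_t[k])
    snap_files[k] <- file.path(out_dir, sprintf("snapshot_%04d.ppm", k))
    write_snapshot(s, snap_files[k])
    utc_sod <- (start_time + ev_t[k] - leap_seconds) %% 86400
    gga <- format_nmea_gga(utc_sod, ev_ll[k, 2], ev_ll[k, 1], 60)
    log_lines[k] <- sprintf("%d %.1f %.1f %s", k, tmin, tmax, gga)
  }
  events_file <- file.path(out_dir, "events.txt")
  writeLines(log_lines, events_file)
  scale_file <- file.path(out_dir, "colorbar.ppm")
  write_color_scale(scale, scale_file)

  pos_file <- file.path(out_dir, "track.pos")
  t_abs <- day0 + start_time + tr_t
  pos_lines <- c(
    "% program   : synthetic flight generator",
    "%  GPST          latitude(deg) longitude(deg)  height(m)   Q  ns   sdn(m)   sde(m)   sdu(m)",
    sprintf("%s %14.9f %14.9f %10.4f %3d %3d %8.4f %8.4f %8.4f",
            # + 0.5 ms because %OS3 truncates instead of rounding
            format(as.POSIXct(t_abs + 5e-4, origin = "1970-01-01", tz = "UTC"),
                   "%Y/%m/%d %H:%M:%OS3"),
            tr_ll[, 2], tr_ll[, 1], 60, 1L, 14L, 0.008, 0.008, 0.02)
  )
  writeLines(pos_lines, pos_file)

  truth <- tibble::tibble(
    snapshot_id = seq_len(n_ev),
    time = day0 + start_time + ev_t,
    x = ev_xy[, 1], y = ev_xy[, 2],
    lon = ev_ll[, 1], lat = ev_ll[, 2],
    t_min = ranges[, 1], t_max = ranges[, 2]
  )
  list(events_file = events_file, pos_file = pos_file,
       scale_file = scale_file, snapshot_files = snap_files,
       truth = truth,
       common_range = c(t_min = min(ranges[, 1]), t_max = max(ranges[, 2])))
}

# serpentine waypoint polyline over the extent, parameterized on [0, 1]
serpentine_path <- function(extent, n_events) {
  n_lines <- max(2, ceiling(sqrt(n_events / 2)))
  ys <- seq(extent[2] * 0.1, extent[2] * 0.9, length.out = n_lines)
  xs <- c(extent[1] * 0.1, extent[1] * 0.9)
  wp <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    x <- if (i %% 2 == 1) xs else rev(xs)
    rbind(c(x[1], ys[i]), c(x[2], ys[i]))
  }))
  seglen <- sqrt(rowSums(diff(wp)^2))
  list(wp = wp, s = c(0, cumsum(seglen)) / sum(seglen))
}

path_at <- function(path, frac) {
  frac <- pmin(pmax(frac, 0), 1)
  x <- stats::approx(path$s, path$wp[, 1], xout = frac, rule = 2)$y
  y <- stats::approx(path$s, path$wp[, 2], xout = frac, rule = 2)$y
  cbind(x, y)
}

#' Synthesize an RGB scene with known cover
#'
#' Paints green vegetation (high VARI) over gray soil according to a
#' per-pixel cover probability, giving an RGB raster whose [green_mask()]
#' fraction is known by construction.
#'
#' @param cover `et_raster` of cover fraction in [0, 1] (the probability a
#'   sub-pixel is vegetated).
#' @param res output pixel size (finer than `cover`'s, integer ratio).
#' @param seed RNG seed.
#' @return 3-band byte `et_raster` and the realized fine-scale mask, as a
#'   list `(rgb, mask)`.
#' @export
synth_rgb_scene <- function(cover, res, seed = 1L) {
  stopifnot(inherits(cover, "et_raster"))
  f <- cover$res / res
  if (abs(f - round(f)) > 1e-9) stop("res must divide the cover resolution")
  f <- round(f)
  d <- dim(cover$values) * f
  p <- cover$values[rep(seq_len(nrow(cover$values)), each = f),
                    rep(seq_len(ncol(cover$values)), each = f)]
  withr::with_seed(seed, {
    veg <- matrix(stats::runif(length(p)) < p, d[1], d[2])
  })
  rgb <- array(0L, dim = c(d[1], d[2], 3))
  rgb[, , 1] <- ifelse(veg, 60L, 120L)
  rgb[, , 2] <- ifelse(veg, 150L, 120L)
  rgb[, , 3] <- ifelse(veg, 50L, 115L)
  list(rgb = et_raster(rgb, xmin = cover$xmin, ymax = cover$ymax, res = res,
                       crs = cover$crs),
       mask = et_raster(veg + 0, xmin = cover$xmin, ymax = cover$ymax,
                        res = res, crs = cover$crs))
}

#' Synthesize eddy-covariance records from flux truth
#'
#' Builds EC half-hour records whose residual-closed latent heat equals the
#' disk-averaged truth latent heat over each footprint: `Rn` and `G` are
#' the disk averages of the truth bands, `H` is set to
#' `Rn - G - LE_disk + noise`, and the reported (unclosed) `LE` is scaled
#' by `1 - imbalance_fraction` to mimic the familiar closure gap. With
#' zero noise, validating the truth raster against the closed records gives
#' RMSE 0 regardless of the imbalance.
#'
#' @param truth a `flux_raster` of truth fluxes.
#' @param specs list of [footprint_spec()]s, one record each.
#' @param imbalance_fraction fraction of LE missing from the reported
#'   (unclosed) latent heat.
#' @param noise_sd Gaussian noise (W/m2) added to the measured sensible
#'   heat.
#' @param seed RNG seed.
#' @return tibble with `time`, `rn`, `g`, `h_ec`, `le_ec`,
#'   `wind_direction`, `peak_distance` - the input expected by
#'   [close_ec_balance()].
#' @export
synth_ec_series <- function(truth, specs, imbalance_fraction = 0.2,
                            noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "flux_raster"))
  if (inherits(specs, "footprint_spec")) specs <- list(specs)
  withr::with_seed(seed, {
    noise <- stats::rnorm(length(specs), 0, noise_sd)
  })
  purrr::imap_dfr(specs, function(sp, i) {
    mask <- footprint_disk(sp, truth)
    le <- average_over_mask(flux_band(truth, "le"), mask)$mean
    rn <- average_over_mask(flux_band(truth, "rn"), mask)$mean
    g <- average_over_mask(flux_band(truth, "g"), mask)$mean
    h <- rn - g - le + noise[i]
    tibble::tibble(time = i * 1800, rn = rn, g = g, h_ec = h,
                   le_ec = (1 - imbalance_fraction) * le,
                   wind_direction = sp$wind_direction,
                   peak_distance = sp$peak_distance)
  })
}
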