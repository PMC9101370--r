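#' Micrometeorological record for a flight
#'
#' Tower measurements driving the energy balance: air temperature, wind
#' speed, pressure, actual vapor pressure and incoming shortwave radiation,
#' plus the measurement heights and canopy height.
#'
#' @param t_air air temperature, degrees C.
#' @param wind wind speed, m/s (floored at 0.1 m/s to keep the resistance
#'   network non-singular).
#' @param pressure air pressure, hPa (800-1100).
#' @param e_a actual vapor pressure, hPa.
#' @param s_dn incoming solar (shortwave) radiation, W/m2.
#' @param z_u,z_t wind / temperature measurement heights, m.
#' @param h_c canopy height, m.
#' @param time record time (free scale), optional.
#' @return a `micromet` object (named list).
#' @export
micromet <- function(t_air, wind, pressure, e_a, s_dn,
                     z_u = 2, z_t = 2, h_c = 0.3, time = NA_real_) {
  stopifnot(s_dn >= 0, pressure >= 800, pressure <= 1100, e_a > 0,
            h_c > 0, z_u > h_c, z_t > h_c)
  structure(list(t_air = t_air, wind = max(wind, 0.1), pressure = pressure,
                 e_a = e_a, s_dn = s_dn, z_u = z_u, z_t = z_t, h_c = h_c,
                 time = time),
            class = "micromet")
}

#' Two-source energy balance parameters
#'
#' All tunable constants of the solver, with the classical defaults of the
#' Priestley-Taylor two-source family: `alpha_pt` 1.26 (Priestley-Taylor
#' coefficient), `kappa_s` 0.45 (net-radiation extinction through the
#' canopy), `c_g` 0.35 (ground heat flux as a fraction of soil net
#' radiation), emissivities 0.98 (canopy) / 0.95 (soil), surface albedo
#' 0.23, momentum roughness `z0m = 0.125 h_c`, displacement `d = 0.65 h_c`,
#' `kB^-1 = 2` (so `z0h = z0m / e^2`), leaf size 0.1 m, the Norman-style
#' soil-resistance coefficients, and the stability-iteration controls.
#'
#' @param ... overrides of any default, by name.
#' @return a `tseb_parameters` object (named list).
#' @export
tseb_parameters <- function(...) {
  p <- list(
    alpha_pt = 1.26, kappa_s = 0.45, c_g = 0.35,
    emis_c = 0.98, emis_s = 0.95, albedo = 0.23,
    z0m_ratio = 0.125, d_ratio = 0.65, kB_inv = 2,
    leaf_size = 0.1, c_prime = 90, rss_a = 0.004, rss_b = 0.012,
    max_iterations = 100L, l_tolerance = 1e-3,
    f_theta_max = 0.95, alpha_step = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$alpha_pt > 0, p$alpha_pt <= 2, p$kappa_s > 0, p$c_g > 0)
  structure(p, class = "tseb_parameters")
}

#' Read a key = value run configuration
#'
#' Plain-text run configuration, one `key = value` per line, `#` comments.
#' Recognized keys override [tseb_parameters()] defaults; unknown keys
#' produce a warning and are ignored; unparseable numeric values are an
#' error naming the key.
#'
#' @param path text file.
#' @return a `tseb_parameters` object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  defaults <- tseb_parameters()
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(defaults)) {
      warning("unknown configuration key '", key, "' ignored")
      next
    }
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("unparseable value for key '", key, "': '", val, "'")
    if (key == "max_iterations") num <- as.integer(num)
    over[[key]] <- num
  }
  do.call(tseb_parameters, over)
}

# physical constants
.sigma_sb <- 5.670374419e-8   # Stefan-Boltzmann, W/m2/K4
.von_karman <- 0.4
.gravity <- 9.81
.r_dry <- 287.04              # gas constant of dry air, J/kg/K

#' Psychrometric support quantities
#'
#' Saturation vapor pressure slope (Magnus form), psychrometric constant,
#' moist-air density and specific heat at the given state.
#'
#' @param t_air air temperature, degrees C (within -40..60).
#' @param pressure air pressure, hPa.
#' @param e_a actual vapor pressure, hPa (used for the air density).
#' @return list with `delta` (hPa/K), `gamma` (hPa/K), `rho_air` (kg/m3),
#'   `c_p` (J/kg/K), `lambda_v` (J/kg) and `e_sat` (hPa).
#' @export
psychrometrics <- function(t_air, pressure, e_a = 0) {
  if (t_air < -40 || t_air > 60) stop("air temperature out of range [-40, 60] C")
  e_sat <- 6.112 * exp(17.62 * t_air / (243.12 + t_air))
  delta <- e_sat * 17.62 * 243.12 / (243.12 + t_air)^2
  lambda_v <- (2.501 - 0.002361 * t_air) * 1e6
  c_p <- 1013
  gamma <- c_p * pressure / (0.622 * lambda_v)
  t_k <- t_air + 273.15
  rho_air <- pressure * 100 / (.r_dry * t_k) * (1 - 0.378 * e_a / pressure)
  list(delta = delta, gamma = gamma, rho_air = rho_air, c_p = c_p,
       lambda_v = lambda_v, e_sat = e_sat)
}

#' Partition net radiation between canopy and soil
#'
#' Net radiation from shortwave and longwave balance,
#' `Rn = (1 - albedo) * s_dn + eps * (L_dn - sigma * T_rad^4)`, with
#' clear-sky downwelling longwave from air temperature and vapor pressure
#' (Brutsaert emissivity `1.24 (e_a / T_K)^(1/7)`), then Beer-law
#' extinction through the canopy: `Rn_soil = Rn * exp(-kappa_s * LAI)`,
#' `Rn_canopy = Rn - Rn_soil`.
#'
#' @param s_dn incoming solar radiation, W/m2.
#' @param t_air air temperature, degrees C.
#' @param t_rad radiometric surface temperature, degrees C (vectorised).
#' @param e_a vapor pressure, hPa.
#' @param lai leaf area index (vectorised with `t_rad`).
#' @param f_c fractional cover, used to composite the surface emissivity.
#' @param params a [tseb_parameters()].
#' @param l_dn measured downwelling longwave (W/m2) overriding the
#'   clear-sky estimate, optional.
#' @return list with `rn`, `rn_canopy`, `rn_soil` (W/m2).
#' @export
partition_radiation <- function(s_dn, t_air, t_rad, e_a, lai, f_c = 1,
                                params = tseb_parameters(), l_dn = NULL) {
  t_ak <- t_air + 273.15
  if (is.null(l_dn)) {
    eps_a <- 1.24 * (e_a / t_ak)^(1 / 7)
    l_dn <- eps_a * .sigma_sb * t_ak^4
  }
  eps_surf <- f_c * params$emis_c + (1 - f_c) * params$emis_s
  t_rk <- t_rad + 273.15
  rn <- (1 - params$albedo) * s_dn + eps_surf * (l_dn - .sigma_sb * t_rk^4)
  rn_soil <- rn * exp(-params$kappa_s * lai)
  list(rn = rn, rn_canopy = rn - rn_soil, rn_soil = rn_soil)
}

# Businger-Dyer stability correction functions; zeta = z/L
psi_m <- function(zeta) {
  out <- numeric(length(zeta))
  un <- zeta < 0
  x <- (1 - 16 * pmin(zeta, 0))^0.25
  out[un] <- (2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2)[un]
  st <- !un
  out[st] <- -5 * pmin(zeta[st], 1)    # cap strong stability
  out
}

psi_h <- function(zeta) {
  out <- numeric(length(zeta))
  un <- zeta < 0
  x2 <- sqrt(1 - 16 * pmin(zeta, 0))
  out[un] <- (2 * log((1 + x2) / 2))[un]
  st <- !un
  out[st] <- -5 * pmin(zeta[st], 1)
  out
}

#' Resistance network of the two-source model
#'
#' Aerodynamic resistance from the log profile with Monin-Obukhov stability
#' corrections, the canopy boundary-layer resistance and the soil-surface
#' resistance of the series network:
#' \itemize{
#'   \item `R_a = [ln((z_t - d)/z0h) - psi_h] / (k u*)` with
#'     `u* = k u / [ln((z_u - d)/z0m) - psi_m]` (psi terms evaluated as
#'     differences between the upper level and the roughness height);
#'   \item `R_x = c_prime / LAI * sqrt(leaf_size / u_d)` with `u_d` the wind
#'     speed at `d + z0m` from an exponential within-canopy profile;
#'   \item `R_s = 1 / (rss_a + rss_b * u_s)` with `u_s` the wind speed just
#'     above the soil (0.05 m).
#' }
#' A non-finite Obukhov length means neutral conditions (no correction).
#'
#' @param wind wind speed at `z_u`, m/s (>= 0.1).
#' @param z_u,z_t measurement heights, m.
#' @param h_c canopy height, m.
#' @param lai leaf area index used for the within-canopy profile.
#' @param L Obukhov length, m; `Inf`/`NA` for neutral.
#' @param params a [tseb_parameters()].
#' @return list with `r_a`, `r_x`, `r_s` (s/m), `u_star` (m/s) - all finite
#'   and positive.
#' @export
resistances <- function(wind, z_u, z_t, h_c, lai, L = Inf,
                        params = tseb_parameters()) {
  wind <- max(wind, 0.1)
  d <- params$d_ratio * h_c
  z0m <- params$z0m_ratio * h_c
  z0h <- z0m / exp(params$kB_inv)
  k <- .von_karman
  if (!is.finite(L) || L == 0) {
    pm_u <- pm_0 <- ph_t <- ph_0 <- 0
  } else {
    pm_u <- psi_m((z_u - d) / L); pm_0 <- psi_m(z0m / L)
    ph_t <- psi_h((z_t - d) / L); ph_0 <- psi_h(z0h / L)
  }
  denom_m <- log((z_u - d) / z0m) - pm_u + pm_0
  denom_m <- max(denom_m, 0.1)           # keep u* positive under strong instability
  u_star <- k * wind / denom_m
  denom_h <- log((z_t - d) / z0h) - ph_t + ph_0
  denom_h <- max(denom_h, 0.1)
  r_a <- denom_h / (k * u_star)
  # within-canopy wind profile (Goudriaan attenuation)
  u_c <- u_star / k * log((h_c - d) / z0m)
  u_c <- max(u_c, 0.01)
  f_att <- max(lai, 0.1)
  a_att <- 0.28 * f_att^(2 / 3) * h_c^(1 / 3) * params$leaf_size^(-1 / 3)
  u_d <- u_c * exp(-a_att * (1 - (d + z0m) / h_c))
  r_x <- params$c_prime / f_att * sqrt(params$leaf_size / max(u_d, 0.01))
  z_s <- min(0.05, h_c)
  u_s <- u_c * exp(-a_att * (1 - z_s / h_c))
  r_s <- 1 / (params$rss_a + params$rss_b * max(u_s, 1e-3))
  list(r_a = r_a, r_x = r_x, r_s = r_s, u_star = u_star)
}

# nadir view fraction of vegetation in the radiometer field of view
f_theta_nadir <- function(lai, f_c, f_theta_max = 0.95) {
  if (lai <= 0 || f_c <= 0) return(0)
  min(f_c * (1 - exp(-0.5 * lai / f_c)), f_theta_max)
}

# soil temperature (K) from the radiometric decomposition
# T_rad^4 = f_theta T_c^4 + (1 - f_theta) T_s^4
t_soil_from_decomposition <- function(t_rk, t_ck, f_theta) {
  num <- (t_rk^4 - f_theta * t_ck^4) / (1 - f_theta)
  if (num <= 0) return(NA_real_)
  num^0.25
}

#' Solve the two-source energy balance for one pixel
#'
#' Priestley-Taylor flavoured two-source scheme. Net radiation is split
#' between canopy and soil by Beer-law extinction; canopy latent heat is
#' initialized as `LE_c = alpha_pt f_g Delta/(Delta+gamma) Rn_c`; the canopy
#' temperature consistent with that flux through the series resistance
#' network and with the radiometric decomposition
#' `T_rad^4 = f_theta T_c^4 + (1-f_theta) T_s^4` is found by a scalar root
#' solve; soil sensible heat follows from the network, soil latent heat as
#' the residual `LE_s = Rn_s - G - H_s` with `G = c_g Rn_s`. A negative
#' `LE_s` (a drying soil cannot condense) triggers stepwise reduction of
#' `alpha_pt` (0.1 decrements); if `LE_s` is still negative at alpha 0 it is
#' zeroed and `H_s` becomes the residual. The Obukhov length is iterated to
#' convergence by damped successive substitution. Outputs close the balance
#' `Rn = H + LE + G` identically.
#'
#' @param t_rad radiometric surface temperature, degrees C.
#' @param lai leaf area index, m2/m2.
#' @param f_c fractional cover (0-1).
#' @param f_g green fraction of the cover (0-1).
#' @param met a [micromet()] record.
#' @param params a [tseb_parameters()].
#' @return named list: `rn`, `h`, `le`, `g` (W/m2), `le_c`, `le_s`, `h_c`,
#'   `h_s`, `t_c`, `t_s` (degrees C), `alpha_used`, `iterations`,
#'   `converged`.
#' @export
tseb_pt_pixel <- function(t_rad, lai, f_c, f_g, met, params = tseb_parameters()) {
  stopifnot(inherits(met, "micromet"))
  if (!is.finite(t_rad)) stop("t_rad must be finite")
  psy <- psychrometrics(met$t_air, met$pressure, met$e_a)
  rad <- partition_radiation(met$s_dn, met$t_air, t_rad, met$e_a, lai,
                             f_c, params)
  t_ak <- met$t_air + 273.15
  t_rk <- t_rad + 273.15
  rho_cp <- psy$rho_air * psy$c_p
  g_flux <- params$c_g * rad$rn_soil
  f_th <- f_theta_nadir(lai, f_c, params$f_theta_max)
  bare <- lai <= 1e-6 || f_c <= 1e-6 || f_th <= 0

  L <- Inf
  inv_l <- 0
  out <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    res <- resistances(met$wind, met$z_u, met$z_t, met$h_c, lai, L, params)
    if (bare) {
      t_sk <- t_rk
      h_s <- rho_cp * (t_sk - t_ak) / (res$r_a + res$r_s)
      le_s <- rad$rn_soil - g_flux - h_s
      alpha <- 0
      if (le_s < 0) { le_s <- 0; h_s <- rad$rn_soil - g_flux }
      out <- list(h_c = 0, h_s = h_s, le_c = 0, le_s = le_s,
                  t_ck = NA_real_, t_sk = t_sk, alpha = alpha)
    } else {
      out <- solve_canopy_soil(t_rk, t_ak, rad, g_flux, f_th, f_g,
                               rho_cp, psy, res, params)
    }
    h_tot <- out$h_c + out$h_s
    inv_l_new <- if (abs(h_tot) < 1e-3) 0 else
      -(.von_karman * .gravity * h_tot) / (rho_cp * res$u_star^3 * t_ak)
    # damped successive substitution on 1/L
    inv_l_next <- 0.5 * inv_l + 0.5 * inv_l_new
    rel <- abs(inv_l_next - inv_l) / max(abs(inv_l), 1e-4)
    inv_l <- inv_l_next
    L <- if (inv_l == 0) Inf else 1 / inv_l
    if (rel <= params$l_tolerance) { converged <- TRUE; break }
  }
  h <- out$h_c + out$h_s
  le <- out$le_c + out$le_s
  list(rn = rad$rn, h = h, le = le, g = g_flux,
       le_c = out$le_c, le_s = out$le_s, h_c = out$h_c, h_s = out$h_s,
       t_c = if (is.na(out$t_ck)) NA_real_ else out$t_ck - 273.15,
       t_s = out$t_sk - 273.15,
       alpha_used = out$alpha, iterations = iter, converged = converged)
}

# one pass of the vegetated solution at fixed resistances:
# alpha-reduction loop around the canopy-temperature root solve
solve_canopy_soil <- function(t_rk, t_ak, rad, g_flux, f_th, f_g,
                              rho_cp, psy, res, params) {
  pt_frac <- f_g * psy$delta / (psy$delta + psy$gamma)
  t_ac <- function(t_ck, t_sk)
    (t_ak / res$r_a + t_ck / res$r_x + t_sk / res$r_s) /
    (1 / res$r_a + 1 / res$r_x + 1 / res$r_s)
  t_c_upper <- (t_rk^4 / f_th)^0.25 - 1e-6
  alpha <- params$alpha_pt
  repeat {
    h_c_target <- rad$rn_canopy * (1 - alpha * pt_frac)
    gfun <- function(t_ck) {
      t_sk <- t_soil_from_decomposition(t_rk, t_ck, f_th)
      rho_cp * (t_ck - t_ac(t_ck, t_sk)) / res$r_x - h_c_target
    }
    lower <- min(t_ak, t_rk) - 60
    f_lo <- gfun(lower); f_hi <- gfun(t_c_upper)
    if (is.finite(f_lo) && is.finite(f_hi) && f_lo * f_hi < 0) {
      t_ck <- stats::uniroot(gfun, c(lower, t_c_upper), tol = 1e-8)$root
    } else {
      # no interior root: take the admissible endpoint closer to balance
      t_ck <- if (!is.finite(f_lo) || (is.finite(f_hi) && abs(f_hi) < abs(f_lo)))
        t_c_upper else lower
    }
    t_sk <- t_soil_from_decomposition(t_rk, t_ck, f_th)
    if (is.na(t_sk)) t_sk <- t_ck
    tac <- t_ac(t_ck, t_sk)
    h_c <- rho_cp * (t_ck - tac) / res$r_x
    h_s <- rho_cp * (t_sk - tac) / res$r_s
    le_c <- rad$rn_canopy - h_c
    le_s <- rad$rn_soil - g_flux - h_s
    if (le_s >= -1e-9 || alpha <= 0) break
    alpha <- max(alpha - params$alpha_step, 0)
  }
  if (le_s < 0) { le_s <- 0; h_s <- rad$rn_soil - g_flux }
  list(h_c = h_c, h_s = h_s, le_c = le_c, le_s = le_s,
       t_ck = t_ck, t_sk = t_sk, alpha = alpha)
}

#' Run the two-source model over a scene
#'
#' Applies [tseb_pt_pixel()] to every pixel of co-registered surface
#' inputs. Nodata in any input propagates to nodata fluxes. The result is
#' deterministic in its inputs.
#'
#' @param inputs a [surface_inputs()] bundle.
#' @param met a [micromet()] record.
#' @param params a [tseb_parameters()].
#' @return an object of class `flux_raster`: an `et_raster` with bands
#'   `rn`, `h`, `le`, `g` plus a `converged` band (1/0).
#' @export
run_tseb <- function(inputs, met, params = tseb_parameters()) {
  stopifnot(inherits(inputs, "surface_inputs"))
  d <- dim(inputs$t_rad$values)
  for (nm in c("lai", "f_c", "f_g"))
    if (!all(dim(inputs[[nm]]$values)[1:2] == d))
      stop("surface input '", nm, "' grid does not match t_rad")
  n <- prod(d)
  tr <- as.vector(inputs$t_rad$values)
  la <- as.vector(inputs$lai$values)
  fc <- as.vector(inputs$f_c$values)
  fg <- as.vector(inputs$f_g$values)
  bands <- matrix(NA_real_, n, 5)
  ok <- is.finite(tr) & is.finite(la) & is.finite(fc) & is.finite(fg)
  for (i in which(ok)) {
    p <- tseb_pt_pixel(tr[i], la[i], fc[i], fg[i], met, params)
    bands[i, ] <- c(p$rn, p$h, p$le, p$g, as.numeric(p$converged))
  }
  arr <- array(bands, dim = c(d[1], d[2], 5))
  r <- et_raster(arr, xmin = inputs$t_rad$xmin, ymax = inputs$t_rad$ymax,
                 res = inputs$t_rad$res, crs = inputs$t_rad$crs)
  r$band_names <- c("rn", "h", "le", "g", "converged")
  class(r) <- c("flux_raster", class(r))
  r
}

#' @export
print.flux_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<flux_raster> %d x %d px, res %g m, bands %s\n",
              d[1], d[2], x$res, paste(x$band_names, collapse = "/")))
  for (b in c("rn", "h", "le", "g")) {
    v <- raster_band(x, match(b, x$band_names))
    cat(sprintf("  %-2s: mean %7.1f, range [%7.1f, %7.1f] W/m2\n",
                toupper(b), mean(v, na.rm = TRUE),
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  conv <- raster_band(x, match("converged", x$band_names))
  cat(sprintf("  converged: %.1f%%\n", 100 * mean(conv, na.rm = TRUE)))
  invisible(x)
}

#' Extract a named band of a flux raster
#' @param fluxes a `flux_raster` from [run_tseb()].
#' @param band one of `"rn"`, `"h"`, `"le"`, `"g"`, `"converged"`.
#' @return a single-band `et_raster`.
#' @export
flux_band <- function(fluxes, band) {
  stopifnot(inherits(fluxes, "flux_raster"))
  i <- match(band, fluxes$band_names)
  if (is.na(i)) stop("unknown band '", band, "'")
  et_raster(fluxes$values[, , i], xmin = fluxes$xmin, ymax = fluxes$ymax,
            res = fluxes$res, crs = fluxes$crs)
}

#' Write a flux raster to disk
#'
#' One ASCII grid per band (`<stem>_rn.asc`, `_h`, `_le`, `_g`,
#' `_converged`), all on the same grid.
#'
#' @param fluxes a `flux_raster`.
#' @param stem output path stem.
#' @return the written paths, invisibly.
#' @export
write_flux_raster <- function(fluxes, stem) {
  stopifnot(inherits(fluxes, "flux_raster"))
  paths <- character(0)
  for (b in fluxes$band_names) {
    p <- paste0(stem, "_", b, ".asc")
    write_ascii_grid(flux_band(fluxes, b), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
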