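#' Parse an NMEA 0183 GGA sentence
#'
#' Verifies the `*hh` XOR checksum, converts `ddmm.mmmm` fields to decimal
#' degrees and returns time-of-day, position, fix quality and satellite
#' count. Sentences failing the checksum or structurally malformed return
#' `NULL`.
#'
#' @param sentence a single `$G?GGA` sentence string.
#' @return a list with `utc_sod` (UTC seconds of day), `lat`, `lon` (decimal
#'   degrees, signed), `alt` (m), `quality` (integer GGA fix code),
#'   `n_satellites`; or `NULL` if invalid.
#' @export
parse_nmea_gga <- function(sentence) {
  sentence <- trimws(sentence)
  if (!grepl("^\\$[A-Z]{2}GGA,", sentence)) return(NULL)
  star <- regexpr("\\*", sentence)
  if (star < 0) return(NULL)
  body <- substr(sentence, 2, star - 1)
  claimed <- suppressWarnings(strtoi(substr(sentence, star + 1, star + 2), 16L))
  actual <- Reduce(bitwXor, as.integer(charToRaw(body)))
  if (is.na(claimed) || claimed != actual) return(NULL)
  f <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (length(f) < 10) return(NULL)
  hms <- suppressWarnings(as.numeric(f[2]))
  lat <- nmea_deg(f[3], f[4])
  lon <- nmea_deg(f[5], f[6])
  qual <- suppressWarnings(as.integer(f[7]))
  nsat <- suppressWarnings(as.integer(f[8]))
  alt <- suppressWarnings(as.numeric(f[10]))
  if (anyNA(c(hms, lat, lon))) return(NULL)
  utc_sod <- (hms %/% 10000) * 3600 + (hms %/% 100 %% 100) * 60 + hms %% 100
  list(utc_sod = utc_sod, lat = lat, lon = lon, alt = alt,
       quality = qual, n_satellites = nsat)
}

# ddmm.mmmm (+ hemisphere letter) -> signed decimal degrees
nmea_deg <- function(field, hemi) {
  v <- suppressWarnings(as.numeric(field))
  if (is.na(v)) return(NA_real_)
  deg <- v %/% 100 + (v %% 100) / 60
  if (hemi %in% c("S", "W")) deg <- -deg
  deg
}

nmea_checksum <- function(body) {
  sprintf("%02X", Reduce(bitwXor, as.integer(charToRaw(body))))
}

# build a GGA sentence (used by the synthetic flight generator)
format_nmea_gga <- function(utc_sod, lat, lon, alt, quality = 1L, nsat = 12L) {
  h <- floor(utc_sod / 3600) %% 24
  m <- floor(utc_sod / 60) %% 60
  s <- utc_sod %% 60
  body <- sprintf("GPGGA,%02d%02d%05.2f,%s,%s,%s,%s,%d,%02d,0.9,%.1f,M,0.0,M,,",
                  h, m, s,
                  deg_to_nmea(lat, 2), if (lat >= 0) "N" else "S",
                  deg_to_nmea(lon, 3), if (lon >= 0) "E" else "W",
                  quality, nsat, alt)
  paste0("$", body, "*", nmea_checksum(body))
}

deg_to_nmea <- function(deg, width) {
  a <- abs(deg)
  d <- floor(a)
  m <- (a - d) * 60
  sprintf(paste0("%0", width, "d%09.6f"), d, m)
}

#' Parse a camera event log
#'
#' The onboard logger writes one line per thermal snapshot: the serial
#' number, the frame's minimum and maximum temperature, and the NMEA GGA
#' sentence polled at trigger time, whitespace separated. Malformed lines
#' (wrong field count, unparseable numbers) and sentences failing the NMEA
#' checksum do not abort the parse: they are collected in a rejects report
#' attached to the result.
#'
#' @param path text file path.
#' @param date flight date (`"YYYY-MM-DD"`, UTC) used to lift NMEA time of
#'   day to absolute UTC seconds; `NULL` leaves `time` as seconds of day.
#' @return a tibble with columns `snapshot_id`, `t_min`, `t_max`, `time`
#'   (UTC seconds), `lat`, `lon`, `alt`, `nmea_quality` (`NA` where the
#'   position was absent/corrupt), ordered by `snapshot_id`. The attribute
#'   `"rejects"` is a tibble of line numbers and reasons.
#' @export
parse_event_log <- function(path, date = NULL) {
  if (!file.exists(path)) stop("cannot read event log: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  day0 <- if (is.null(date)) 0 else
    as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC"))
  recs <- vector("list", length(lines))
  rejects <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3) {
      rejects[[length(rejects) + 1]] <- tibble::tibble(line = i, reason = "too few fields")
      next
    }
    id <- suppressWarnings(as.integer(tok[1]))
    tmin <- suppressWarnings(as.numeric(tok[2]))
    tmax <- suppressWarnings(as.numeric(tok[3]))
    if (anyNA(c(id, tmin, tmax)) || tmax <= tmin) {
      rejects[[length(rejects) + 1]] <- tibble::tibble(line = i, reason = "bad id or temperature fields")
      next
    }
    gga <- if (length(tok) >= 4) parse_nmea_gga(tok[4]) else NULL
    if (length(tok) >= 4 && is.null(gga))
      rejects[[length(rejects) + 1]] <- tibble::tibble(line = i, reason = "invalid NMEA sentence")
    recs[[i]] <- tibble::tibble(
      snapshot_id = id, t_min = tmin, t_max = tmax,
      time = if (is.null(gga)) NA_real_ else day0 + gga$utc_sod,
      lat = if (is.null(gga)) NA_real_ else gga$lat,
      lon = if (is.null(gga)) NA_real_ else gga$lon,
      alt = if (is.null(gga)) NA_real_ else gga$alt,
      nmea_quality = if (is.null(gga)) NA_integer_ else gga$quality
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(recs), .data$snapshot_id)
  attr(out, "rejects") <- dplyr::bind_rows(rejects)
  out
}

#' Parse an RTKLIB-style .pos track
#'
#' Whitespace-delimited post-processed positions, header lines starting
#' with `%`. Columns: date, time (GPST), latitude, longitude, height,
#' quality flag Q, satellite count, and the N/E/U standard deviations.
#' Times are converted to a single numeric epoch scale (seconds).
#'
#' @param path .pos file path.
#' @return tibble with `time` (GPST seconds), `lat`, `lon`, `height`,
#'   `quality` (`"fix"`, `"float"`, `"single"`), `n_satellites`, `sd_n`,
#'   `sd_e`, `sd_u`.
#' @export
parse_pos <- function(path) {
  if (!file.exists(path)) stop("cannot read .pos file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (length(data_lines) == 0) {
    return(tibble::tibble(time = numeric(), lat = numeric(), lon = numeric(),
                          height = numeric(), quality = character(),
                          n_satellites = integer(), sd_n = numeric(),
                          sd_e = numeric(), sd_u = numeric()))
  }
  q_map <- c("1" = "fix", "2" = "float", "5" = "single")
  recs <- vector("list", length(data_lines))
  for (i in seq_along(data_lines)) {
    tok <- strsplit(trimws(data_lines[i]), "\\s+")[[1]]
    if (length(tok) < 10)
      stop("malformed .pos data line ", i, ": too few columns")
    t <- as.numeric(as.POSIXct(paste(tok[1], tok[2]),
                               format = "%Y/%m/%d %H:%M:%OS", tz = "UTC"))
    q <- q_map[tok[6]]
    if (is.na(q))
      stop("unknown quality code Q=", tok[6], " on .pos data line ", i)
    recs[[i]] <- tibble::tibble(
      time = t, lat = as.numeric(tok[3]), lon = as.numeric(tok[4]),
      height = as.numeric(tok[5]), quality = unname(q),
      n_satellites = as.integer(tok[7]),
      sd_n = as.numeric(tok[8]), sd_e = as.numeric(tok[9]),
      sd_u = as.numeric(tok[10])
    )
  }
  dplyr::bind_rows(recs)
}

#' Convert a GNSS solution quality code to a position accuracy
#'
#' The mosaicking software expects per-camera accuracies as a distance, so
#' the PPK quality flags are mapped to fixed values: fix 0.5 m, float 2 m,
#' single 10 m.
#'
#' @param q character vector of quality codes (`"fix"`, `"float"`,
#'   `"single"`).
#' @return numeric accuracies in metres.
#' @export
quality_to_accuracy <- function(q) {
  map <- c(fix = 0.5, float = 2, single = 10)
  out <- map[q]
  if (anyNA(out)) stop("unknown quality code(s): ",
                       paste(unique(q[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Join camera trigger events to a PPK track
#'
#' Each event is matched to the nearest-in-time track point (ties resolve
#' to the earlier point); events farther than `tolerance` from every track
#' point are kept but flagged unmatched. Event times from the NMEA log are
#' UTC while the post-processed track is on GPS time; `leap_seconds` is
#' added to event times to reconcile the two scales.
#'
#' @param events tibble from [parse_event_log()].
#' @param track tibble from [parse_pos()], non-empty and time-sorted.
#' @param tolerance maximum |event - track| time difference in seconds for a
#'   match (default 0.2 s, one track interval at 5 Hz).
#' @param leap_seconds GPST - UTC offset applied to event times (default 18).
#' @return tibble with one row per event: `snapshot_id`, `time` (GPST),
#'   `lat`, `lon`, `height`, `quality`, `accuracy` (m, see
#'   [quality_to_accuracy()]), `source_track_time`, `dt` (signed event -
#'   track seconds) and `matched`.
#' @export
match_events <- function(events, track, tolerance = 0.2, leap_seconds = 18) {
  stopifnot(nrow(track) > 0)
  if (is.unsorted(track$time)) stop("track must be time-sorted")
  t_ev <- events$time + leap_seconds
  tt <- track$time
  pos <- findInterval(t_ev, tt)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(tt))
  d_lo <- abs(t_ev - tt[lo])
  d_hi <- abs(t_ev - tt[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)   # tie -> earlier point
  dt <- t_ev - tt[nearest]
  matched <- !is.na(dt) & abs(dt) <= tolerance
  idx <- ifelse(matched, nearest, NA_integer_)
  accuracy <- rep(NA_real_, length(idx))
  accuracy[matched] <- quality_to_accuracy(track$quality[idx[matched]])
  tibble::tibble(
    snapshot_id = events$snapshot_id,
    time = t_ev,
    lat = track$lat[idx],
    lon = track$lon[idx],
    height = track$height[idx],
    quality = track$quality[idx],
    accuracy = accuracy,
    source_track_time = tt[idx],
    dt = ifelse(matched, dt, NA_real_),
    matched = matched
  )
}

#' Write camera positions for the mosaicking software
#'
#' One row per snapshot: `label, lon, lat, alt, accuracy_m`, ordered by
#' snapshot id. Refuses to write if unmatched events are present unless
#' `allow_partial = TRUE` (unmatched rows are then dropped).
#'
#' @param events tibble from [match_events()].
#' @param path output CSV path.
#' @param allow_partial drop unmatched events instead of erroring.
#' @return the written tibble, invisibly.
#' @export
write_camera_positions <- function(events, path, allow_partial = FALSE) {
  if (any(!events$matched)) {
    if (!allow_partial)
      stop(sum(!events$matched), " unmatched event(s); use allow_partial = TRUE to drop them")
    events <- dplyr::filter(events, .data$matched)
  }
  out <- events |>
    dplyr::arrange(.data$snapshot_id) |>
    dplyr::transmute(label = .data$snapshot_id, lon = .data$lon,
                     lat = .data$lat, alt = .data$height,
                     accuracy_m = .data$accuracy)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Fit a planar affine alignment from control-point pairs
#'
#' Least-squares 2-D affine transform mapping source coordinates onto
#' target coordinates, as used to align the thermal mosaic to the RGB
#' mosaic from marked tie points.
#'
#' @param pairs data frame with columns `sx`, `sy` (source) and `tx`, `ty`
#'   (target); at least 3 non-collinear pairs.
#' @return an object of class `affine2d`: `A` (2x2 matrix), `b` (length-2
#'   offset), `rms` (residual root mean square), `n`. Supports
#'   [predict()][predict.affine2d], [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
fit_alignment <- function(pairs) {
  stopifnot(all(c("sx", "sy", "tx", "ty") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 control-point pairs")
  X <- cbind(1, pairs$sx, pairs$sy)
  if (qr(X)$rank < 3) stop("control points are collinear")
  cx <- qr.solve(X, pairs$tx)
  cy <- qr.solve(X, pairs$ty)
  A <- rbind(cx[2:3], cy[2:3])
  b <- c(cx[1], cy[1])
  pred <- X %*% cbind(cx, cy)
  res2 <- (pred[, 1] - pairs$tx)^2 + (pred[, 2] - pairs$ty)^2
  structure(list(A = A, b = b, rms = sqrt(mean(res2)), n = nrow(pairs)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> target = A %*% source + b\n")
  cat(sprintf("  A = [%9.6f %9.6f; %9.6f %9.6f], b = [%g, %g]\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b[1], x$b[2]))
  cat(sprintf("  residual RMS %.4g over %d pairs\n", x$rms, x$n))
  invisible(x)
}

#' Apply a fitted affine alignment
#' @param object an `affine2d` from [fit_alignment()].
#' @param newdata data frame with columns `sx`, `sy`.
#' @param ... unused.
#' @return tibble with transformed `tx`, `ty`.
#' @export
predict.affine2d <- function(object, newdata, ...) {
  p <- t(object$A %*% rbind(newdata$sx, newdata$sy) + object$b)
  tibble::tibble(tx = p[, 1], ty = p[, 2])
}

#' Spatial error of ground control points
#'
#' Distance between each GCP's surveyed position and its position read off
#' the orthomosaic, plus mean and standard deviation over the held-out
#' subset (GCPs excluded from mosaicking, the only ones giving an unbiased
#' accuracy estimate).
#'
#' @param gcps data frame with columns `id`, `lon`, `lat` (surveyed),
#'   `mosaic_lon`, `mosaic_lat`, and logical `held_out`.
#' @param method `"haversine"` (sphere of radius 6378137 m) or `"geodesic"`
#'   (WGS-84 ellipsoid via [geosphere::distGeo()]).
#' @return tibble of per-GCP distances (m) with columns of `gcps` plus
#'   `distance`; attributes `avg_selected` and `sd_selected` hold the
#'   held-out summary (`NA` when no GCP is held out).
#' @export
gcp_spatial_error <- function(gcps, method = c("haversine", "geodesic")) {
  method <- match.arg(method)
  stopifnot(nrow(gcps) >= 1,
            all(c("lon", "lat", "mosaic_lon", "mosaic_lat") %in% names(gcps)))
  p1 <- cbind(gcps$lon, gcps$lat)
  p2 <- cbind(gcps$mosaic_lon, gcps$mosaic_lat)
  d <- if (method == "haversine") geosphere::distHaversine(p1, p2)
       else geosphere::distGeo(p1, p2)
  out <- dplyr::mutate(tibble::as_tibble(gcps), distance = d)
  held <- if ("held_out" %in% names(gcps)) gcps$held_out else rep(FALSE, nrow(gcps))
  attr(out, "avg_selected") <- if (any(held)) mean(d[held]) else NA_real_
  attr(out, "sd_selected") <- if (sum(held) > 1) stats::sd(d[held]) else NA_real_
  out
}
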