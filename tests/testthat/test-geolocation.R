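make_gga <- function(utc_sod, lat, lon, alt = 60) {
  etmap:::format_nmea_gga(utc_sod, lat, lon, alt)
}

test_that("NMEA GGA parsing converts ddmm.mm to decimal degrees and checks the checksum", {
  g <- parse_nmea_gga("$GPGGA,104135.00,4641.40,N,01936.00,E,1,12,0.9,142.0,M,0.0,M,,*5D")
  expect_equal(g$lat, 46 + 41.40 / 60, tolerance = 1e-6 / 46.69)
  expect_equal(g$lon, 19.6, tolerance = 1e-9)
  expect_equal(g$utc_sod, 10 * 3600 + 41 * 60 + 35)
  expect_equal(g$quality, 1L)
  # corrupt one character: checksum fails, parse returns NULL
  bad <- sub("4641.40", "4641.41", "$GPGGA,104135.00,4641.40,N,01936.00,E,1,12,0.9,142.0,M,0.0,M,,*5D")
  expect_null(parse_nmea_gga(bad))
  # round trip through the generator
  s <- make_gga(37530.25, -33.8651, 151.2099)
  g2 <- parse_nmea_gga(s)
  expect_equal(g2$lat, -33.8651, tolerance = 1e-7)
  expect_equal(g2$lon, 151.2099, tolerance = 1e-7)
  expect_equal(g2$utc_sod, 37530.25, tolerance = 0.011)
})

test_that("event log parsing keeps malformed lines in a rejects report", {
  f <- withr::local_tempfile(fileext = ".txt")
  ok <- vapply(1:5, function(i)
    sprintf("%d %.1f %.1f %s", i, 20 + i, 30 + i,
            make_gga(36000 + i, 46.69, 19.60)), character(1))
  corrupt <- sub("\\*..$", "*00", make_gga(36010, 46.69, 19.60))
  lines <- c(ok[1:3], paste("6 25.0 35.0", corrupt), "garbage line", ok[4:5])
  writeLines(lines, f)
  ev <- parse_event_log(f, date = "2020-06-20")
  expect_equal(nrow(ev), 6)            # 5 good + 1 with absent position
  expect_equal(ev$snapshot_id, 1:6)
  rej <- attr(ev, "rejects")
  expect_equal(nrow(rej), 2)           # bad checksum + garbage line
  expect_true(is.na(ev$lat[ev$snapshot_id == 6]))
  expect_true(all(ev$t_max > ev$t_min))
  expect_error(parse_event_log(tempfile()), "cannot read")
})

test_that(".pos parsing maps quality codes and preserves 5 Hz spacing", {
  fl <- small_flight()
  tr <- parse_pos(fl$out$pos_file)
  expect_equal(nrow(tr), 301)          # 60 s at 5 Hz, endpoints inclusive
  expect_equal(median(diff(tr$time)), 0.2, tolerance = 1e-6)
  expect_true(all(tr$quality == "fix"))
  # header-only file gives an empty track
  f <- withr::local_tempfile(fileext = ".pos")
  writeLines(c("% header", "%  GPST  lat lon h Q ns sdn sde sdu"), f)
  expect_equal(nrow(parse_pos(f)), 0)
  # Q mapping: 2 -> float, 5 -> single, anything else errors with the line
  f2 <- withr::local_tempfile(fileext = ".pos")
  writeLines(c(
    "% synthetic",
    "2020/06/20 10:00:00.000 46.69 19.60 60.0 2 9 0.1 0.1 0.2",
    "2020/06/20 10:00:00.200 46.69 19.60 60.0 5 5 1.0 1.0 2.0"), f2)
  t2 <- parse_pos(f2)
  expect_equal(t2$quality, c("float", "single"))
  writeLines(c("2020/06/20 10:00:00.000 46.69 19.60 60.0 3 9 0.1 0.1 0.2"), f2)
  expect_error(parse_pos(f2), "Q=3.*line 1")
})

test_that("quality codes convert to the fixed accuracies and nothing else", {
  expect_equal(quality_to_accuracy("fix"), 0.5)
  expect_equal(quality_to_accuracy("float"), 2)
  expect_equal(quality_to_accuracy("single"), 10)
  expect_equal(quality_to_accuracy(c("fix", "single", "float")), c(0.5, 10, 2))
  expect_error(quality_to_accuracy("dgps"), "unknown quality")
})

test_that("event matching picks the nearest track point with earlier-point ties", {
  track <- tibble::tibble(
    time = c(100.0, 100.2, 100.4), lat = c(1, 2, 3), lon = c(1, 2, 3),
    height = 60, quality = c("fix", "float", "single"),
    n_satellites = 10L, sd_n = 0.01, sd_e = 0.01, sd_u = 0.02)
  ev <- tibble::tibble(snapshot_id = 1:3, t_min = 10, t_max = 20,
                       time = c(100.05, 100.1, 105.0) - 18,
                       lat = NA, lon = NA, alt = NA, nmea_quality = 1L)
  m <- match_events(ev, track, tolerance = 0.5)
  expect_equal(m$source_track_time[1], 100.0)   # nearest
  expect_equal(m$source_track_time[2], 100.0)   # exact tie -> earlier
  expect_false(m$matched[3])                    # 4.6 s past track end
  expect_true(all(is.na(m$lat[!m$matched])))
  expect_equal(m$accuracy[1:2], c(0.5, 0.5))
  # order independence: permuting events permutes the result rows only
  m2 <- match_events(ev[c(3, 1, 2), ], track, tolerance = 0.5)
  expect_equal(dplyr::arrange(m2, snapshot_id), m)
})

test_that("simulated flight events all match within half a track interval", {
  fl <- small_flight()
  ev <- parse_event_log(fl$out$events_file, date = "2020-06-20")
  tr <- parse_pos(fl$out$pos_file)
  m <- match_events(ev, tr)
  expect_true(all(m$matched))
  expect_lte(max(abs(m$dt)), 0.1 + 1e-3)
  # matched positions equal the truth table within the pick error
  # (flight speed x half a track interval, plus NMEA rounding)
  speed <- max(sqrt(diff(fl$out$truth$x)^2 + diff(fl$out$truth$y)^2)) /
    diff(fl$out$truth$time[1:2])
  err_m <- geosphere::distHaversine(cbind(m$lon, m$lat),
                                    cbind(fl$out$truth$lon, fl$out$truth$lat))
  expect_lte(max(err_m), speed * 0.1 + 0.05)
})

test_that("camera position CSV is deterministic and refuses unmatched events", {
  fl <- small_flight()
  ev <- parse_event_log(fl$out$events_file, date = "2020-06-20")
  tr <- parse_pos(fl$out$pos_file)
  m <- match_events(ev, tr)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  out <- write_camera_positions(m, f1)
  expect_equal(nrow(out), nrow(ev))
  got <- utils::read.csv(f1)
  expect_equal(names(got), c("label", "lon", "lat", "alt", "accuracy_m"))
  expect_equal(got$accuracy_m, quality_to_accuracy(m$quality))
  write_camera_positions(m, f2)
  expect_identical(readLines(f1), readLines(f2))
  mbad <- m; mbad$matched[3] <- FALSE
  expect_error(write_camera_positions(mbad, f1), "unmatched")
  expect_silent(write_camera_positions(mbad, f1, allow_partial = TRUE))
  expect_equal(nrow(utils::read.csv(f1)), nrow(ev) - 1)
})

test_that("affine alignment recovers exact transforms and reports residual RMS", {
  # identity
  p <- tibble::tibble(sx = c(0, 1, 0, 5), sy = c(0, 0, 1, 7),
                      tx = sx, ty = sy)
  fit <- fit_alignment(p)
  expect_equal(fit$A, diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$b, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$rms, 0, tolerance = 1e-12)
  # pure translation
  pt <- dplyr::mutate(p, tx = sx + 3.5, ty = sy - 1.25)
  ft <- fit_alignment(pt)
  expect_equal(ft$A, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ft$b, c(3.5, -1.25), tolerance = 1e-10)
  # random non-degenerate affines recovered to machine precision
  withr::with_seed(21, {
    for (i in 1:5) {
      A <- matrix(rnorm(4, sd = 2), 2); b <- rnorm(2, sd = 10)
      if (abs(det(A)) < 0.1) A <- A + diag(2)
      s <- matrix(rnorm(12), ncol = 2)
      t <- t(A %*% t(s) + b)
      fx <- fit_alignment(tibble::tibble(sx = s[, 1], sy = s[, 2],
                                         tx = t[, 1], ty = t[, 2]))
      expect_equal(fx$A, A, tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(fx$b, b, tolerance = 1e-9)
    }
  })
  # noisy fit equals the normal-equations solution
  withr::with_seed(22, {
    s <- matrix(runif(40, 0, 100), ncol = 2)
    t <- t(matrix(c(1.01, 0.02, -0.01, 0.99), 2) %*% t(s) + c(2, -3)) +
      matrix(rnorm(40, sd = 0.1), ncol = 2)
  })
  fx <- fit_alignment(tibble::tibble(sx = s[, 1], sy = s[, 2],
                                     tx = t[, 1], ty = t[, 2]))
  X <- cbind(1, s)
  beta <- solve(t(X) %*% X, t(X) %*% t)
  expect_equal(unname(c(fx$b[1], fx$A[1, ])), unname(beta[, 1]), tolerance = 1e-10)
  expect_equal(unname(c(fx$b[2], fx$A[2, ])), unname(beta[, 2]), tolerance = 1e-10)
  pred <- predict(fx, tibble::tibble(sx = s[, 1], sy = s[, 2]))
  expect_equal(fx$rms, sqrt(mean((pred$tx - t[, 1])^2 + (pred$ty - t[, 2])^2)),
               tolerance = 1e-12)
  # degenerate input
  expect_error(fit_alignment(p[1:2, ]), "at least 3")
  coll <- tibble::tibble(sx = 1:5, sy = 2 * (1:5), tx = 1:5, ty = 2 * (1:5))
  expect_error(fit_alignment(coll), "collinear")
})

test_that("GCP spatial error uses geodesic distances and summarizes the held-out set", {
  g0 <- tibble::tibble(id = 1, lon = 19.6, lat = 46.69,
                       mosaic_lon = 19.6, mosaic_lat = 46.69, held_out = TRUE)
  expect_equal(gcp_spatial_error(g0)$distance, 0)
  # one degree of longitude on the equator: haversine closed form
  g1 <- tibble::tibble(id = 1, lon = 0, lat = 0, mosaic_lon = 1,
                       mosaic_lat = 0, held_out = FALSE)
  expect_equal(gcp_spatial_error(g1)$distance, 6378137 * pi / 180,
               tolerance = 1e-9)
  # held-out mean of fabricated distances
  withr::with_seed(30, {
    d_m <- c(0.1, 0.2, 0.3, 0.4)
    lat0 <- 46.69
    g4 <- tibble::tibble(id = 1:4, lon = 19.6, lat = lat0,
                         mosaic_lon = 19.6,
                         mosaic_lat = lat0 + d_m / (6378137 * pi / 180),
                         held_out = TRUE)
  })
  res <- gcp_spatial_error(g4)
  expect_equal(attr(res, "avg_selected"), 0.25, tolerance = 1e-6)
  expect_equal(attr(res, "sd_selected"), sd(d_m), tolerance = 1e-4)
  # distances are symmetric and satisfy the triangle inequality
  withr::with_seed(31, {
    pts <- cbind(runif(9, 19, 20), runif(9, 46, 47))
  })
  for (i in seq(1, 9, 3)) {
    a <- pts[i, ]; b <- pts[i + 1, ]; c <- pts[i + 2, ]
    dab <- geosphere::distHaversine(a, b)
    expect_equal(dab, geosphere::distHaversine(b, a))
    expect_lte(dab, geosphere::distHaversine(a, c) +
                 geosphere::distHaversine(c, b) + 1e-6)
  }
})
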