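test_that("film scans round-trip through 16-bit TIFF and reject other depths", {
  px <- array(40000L, dim = c(10, 10, 3))
  scan <- film_scan(px)
  f <- withr::local_tempfile(fileext = ".tif")
  write_scan(scan, f)
  back <- read_scan(f)
  expect_identical(back$pixels, scan$pixels)

  # arbitrary content round-trips bit-identically
  set.seed(5)
  px2 <- array(sample.int(65536L, 600, replace = TRUE) - 1L, dim = c(10, 20, 3))
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_scan(film_scan(px2), f2)
  expect_identical(read_scan(f2)$pixels, px2)

  # an 8-bit file is refused with the expected bit depth in the message
  f8 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, dim = c(5, 5, 3)), f8, bits.per.sample = 8L)
  expect_error(read_scan(f8), "16-bit")
})

test_that("red-channel ROI means are plain arithmetic means", {
  px <- array(30000L, dim = c(8, 8, 3))
  scan <- film_scan(px)
  expect_equal(red_channel_pv(scan), 30000)
  px[1, 1, 1] <- 20000L
  px[1, 2, 1] <- 40000L
  scan <- film_scan(px)
  expect_equal(red_channel_pv(scan, c(1, 1, 1, 2)), 30000)

  # checkerboard of 0/65535 over an even ROI
  cb <- array(0L, dim = c(4, 4, 3))
  cb[, , 1] <- as.integer((row(cb[, , 1]) + col(cb[, , 1])) %% 2) * 65535L
  expect_equal(red_channel_pv(film_scan(cb)), 32767.5)

  expect_error(red_channel_pv(scan, c(0, 4, 1, 4)), "roi")
  expect_error(red_channel_pv(scan, c(4, 1, 1, 4)), "roi")
})

test_that("netOD is the log ratio of unexposed to exposed pixel values", {
  expect_equal(net_od(40000, 40000), 0)
  expect_equal(net_od(4000, 40000), 1)
  expect_equal(net_od(20000, 40000), log10(2))
  expect_error(net_od(0, 40000), "domain")
  expect_warning(net_od(41000, 40000), "exceeds")

  # translation invariance: netOD equals OD difference for any reference
  set.seed(3)
  pv_e <- runif(20, 5000, 40000)
  pv_u <- runif(20, 30000, 60000)
  for (ref in c(1, 65535, 12345)) {
    od <- function(pv) log10(ref / pv)
    expect_equal(suppressWarnings(net_od(pv_e, pv_u)), od(pv_e) - od(pv_u))
  }
})

test_that("calibration fitting recovers an exact cubic and reports residual R^2", {
  n <- seq(0, 0.6, length.out = 13)
  d <- 100 * n + 300 * n^2 + 50 * n^3
  curve <- fit_calibration(n, d)
  expect_equal(curve$coefficients, c(0, 100, 300, 50), tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_true(curve$monotone)

  set.seed(8)
  curve_n <- fit_calibration(n, d + rnorm(13, sd = 1))
  expect_gte(curve_n$r_squared, 0.9994)

  expect_error(fit_calibration(c(0, 0.1), c(0, 10)), "at least")
  expect_error(fit_calibration(c(0, 0.1, 0.1, 0.2, 0.3), c(0, 1, 1, 2, 3)),
               "distinct")
  expect_warning(fit_calibration(seq(0.1, 0.6, length.out = 8),
                                 50 + 100 * seq(0.1, 0.6, length.out = 8)),
                 "zero-dose")
})

test_that("dose conversion round-trips through the calibration curve", {
  curve <- truth_calibration()
  pv_u <- 42000

  # uniform scan at the unexposed value maps to zero dose
  scan0 <- film_scan(array(as.integer(pv_u), dim = c(5, 5, 3)))
  expect_equal(to_dose(scan0, pv_u, curve), matrix(0, 5, 5))

  # a scan built by inverting the curve at 200 cGy comes back as 200 cGy
  netod <- invert_calibration(curve, 200)
  pv <- as.integer(round(pv_u * 10^(-netod)))
  scan <- film_scan(array(pv, dim = c(4, 6, 3)))
  dm <- to_dose(scan, pv_u, curve)
  expect_lt(max(abs(dm - 200)), 0.1)

  # outside the fitted domain the value is computed but flagged
  pv_hot <- as.integer(round(pv_u * 10^(-0.7)))
  expect_warning(to_dose(film_scan(array(pv_hot, dim = c(2, 2, 3))), pv_u,
                         curve),
                 "extrapolat")

  expect_error(invert_calibration(curve, 1e5), "range error")
})

test_that("profile extraction converts pixels to mm and honors the band", {
  h <- 25.4 / 72
  dm <- matrix(0, nrow = 21, ncol = 101)
  dm[, 36:65] <- 100  # 30-column plateau
  prof <- extract_profile(dm, band_halfwidth_px = 5, dpi = 72)
  expect_s3_class(prof, "dose_profile")
  # plateau extent: 29 inter-sample steps between the outermost plateau pixels
  expect_equal(cross_field_width(prof, 0.5), 29 * h, tolerance = 1e-9)
  # dose-weighted origin sits mid-plateau
  expect_equal(prof$positions_mm[which.max(prof$dose_cGy >= 100)] +
                 29 * h / 2, 0, tolerance = h)

  flat <- extract_profile(matrix(100, 11, 50), band_halfwidth_px = 5)
  expect_true(all(flat$dose_cGy == 100))

  # degenerate band: single row
  dm2 <- matrix(1, 11, 50)
  dm2[6, ] <- 7
  expect_true(all(extract_profile(dm2, band_halfwidth_px = 0)$dose_cGy == 7))
  expect_error(extract_profile(dm2, band_halfwidth_px = 50), "roi")
})

test_that("background-tail matching equalizes films and rejects bad windows", {
  x <- seq(-110, 110, by = 0.5)
  slit <- 400 * exp(-x^2 / (2 * 4^2))
  p1 <- dose_profile(x, slit + 10)
  p2 <- dose_profile(x, slit + 14)
  m1 <- match_background_tail(p1, c(85, 105))
  m2 <- match_background_tail(p2, c(85, 105))
  expect_equal(m1$background_cGy, 10)
  expect_equal(m2$background_cGy, 14)
  tails <- abs(x) >= 85
  expect_lt(max(abs(m1$dose_cGy[tails] - m2$dose_cGy[tails])), 1e-9)
  # constant shift everywhere
  expect_equal(m1$dose_cGy, p1$dose_cGy - 10)

  # a window over the slit is refused
  expect_error(match_background_tail(p1, c(1, 6)), "window error")

  # matching makes the integral invariant to a constant offset
  i1 <- integral_dose(match_background_tail(dose_profile(x, slit + 3),
                                            c(85, 105)))
  i2 <- integral_dose(match_background_tail(dose_profile(x, slit + 23),
                                            c(85, 105)))
  expect_lt(abs(i1 - i2), 1e-9)
})

test_that("cross-field width implements the fractional-peak rule", {
  # rectangle: any threshold below 1 returns the full width
  x <- seq(-50, 50, by = 0.1)
  rect <- dose_profile(x, as.numeric(abs(x) <= 15))
  expect_equal(cross_field_width(rect, 0.005), 30, tolerance = 0.1)
  expect_equal(cross_field_width(rect, 0.9), 30, tolerance = 0.1)

  # Gaussian at half maximum: FWHM = 2*sigma*sqrt(2*log(2))
  xg <- seq(-40, 40, by = 0.01)
  gauss <- dose_profile(xg, exp(-xg^2 / (2 * 25)))
  expect_equal(cross_field_width(gauss, 0.5), 2 * 5 * sqrt(2 * log(2)),
               tolerance = 0.02)

  # rounding grid
  expect_equal(cross_field_width(gauss, 0.5, rounding_mm = 10), 10)
  expect_error(cross_field_width(dose_profile(xg, -exp(-xg^2))),
               "empty-field")
  expect_error(cross_field_width(gauss, 0), "threshold_fraction")
})

test_that("integral dose is the trapezoidal area of the net profile", {
  x <- seq(0, 10, by = 0.1)
  expect_equal(integral_dose(dose_profile(x, rep(1, length(x)))), 10)

  # triangle: peak 100, base 20
  xt <- seq(-10, 10, by = 0.01)
  tri <- pmax(0, 100 * (1 - abs(xt) / 10))
  expect_equal(integral_dose(dose_profile(xt, tri)), 1000, tolerance = 1e-6)

  # erf-edged slit (opaque square edge blurred by a Gaussian): analytic
  # integral equals the unblurred slab area D0 * w
  w <- 12; sigma <- 3; D0 <- 250
  xe <- seq(-80, 80, by = 0.35)
  erf_profile <- D0 / 2 * (pnorm((xe + w / 2) / sigma) -
                             pnorm((xe - w / 2) / sigma)) * 2
  expect_equal(integral_dose(dose_profile(xe, erf_profile)), D0 * w,
               tolerance = 0.001 * D0 * w)

  expect_error(integral_dose(dose_profile(1, 5)), "insufficient")
})

test_that("film DLG regression delegates to the shared fit", {
  integrals <- 55 * (paper_gaps + 1.4)
  est <- derive_dlg_film(paper_gaps, integrals)
  expect_equal(est$dlg_mm, 1.4)
  expect_equal(est$method_tag, "film")
  expect_error(derive_dlg_film(c(2, 4), c(1, 2)), "insufficient")
})
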