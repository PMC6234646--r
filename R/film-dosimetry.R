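#' Read a 48-bit RGB film scan
#'
#' Loads a TIFF scan of a radiochromic film as acquired in transmission mode
#' (16 bits per channel, three channels). Pixel values are loaded verbatim:
#' no gamma, filtering or auto-levels is applied, matching a scan protocol
#' with all scanner image processing disabled. An alpha channel, if present,
#' is ignored.
#'
#' @param path Path to the TIFF file.
#' @param dpi Scan resolution in dots per inch (default 72). TIFF resolution
#'   tags are not trusted; the protocol fixes the resolution.
#' @param orientation_tag `"landscape"` or `"portrait"`; bookkeeping only.
#' @return An object of class `film_scan`: a list with `pixels` (an
#'   `rows x cols x 3` integer array of 16-bit values in 0..65535), `dpi`
#'   and `orientation_tag`.
#' @export
read_scan <- function(path, dpi = 72, orientation_tag = "landscape") {
  if (!file.exists(path)) stop(sprintf("scan file not found: %s", path))
  img <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  if (is.null(bps) || any(bps != 16L))
    stop(sprintf(
      "format error: expected a 16-bit-per-channel TIFF, got %s bits in %s",
      paste(bps, collapse = "/"), path))
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop(sprintf("format error: expected 3 channels (48-bit RGB), got %s in %s",
                 if (length(dim(img)) == 3L) dim(img)[3L] else 1L, path))
  pixels <- round(img[, , 1:3, drop = FALSE] * 65535)
  storage.mode(pixels) <- "integer"
  film_scan(pixels, dpi = dpi, orientation_tag = orientation_tag)
}

#' Construct a film scan object from a pixel array
#'
#' @param pixels `rows x cols x 3` array of integer channel values in
#'   0..65535.
#' @param dpi Resolution in dots per inch.
#' @param orientation_tag `"landscape"` or `"portrait"`.
#' @return A `film_scan` object.
#' @export
film_scan <- function(pixels, dpi = 72, orientation_tag = "landscape") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("pixels must be a rows x cols x 3 array")
  if (any(pixels < 0L) || any(pixels > 65535L))
    stop("channel values must lie in 0..65535")
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0)
    stop("dpi must be a single positive number")
  structure(list(pixels = pixels, dpi = dpi,
                 orientation_tag = match.arg(orientation_tag,
                                             c("landscape", "portrait"))),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<film_scan> %d x %d px, 3 x 16 bit, %g dpi, %s\n",
              d[1], d[2], x$dpi, x$orientation_tag))
  invisible(x)
}

#' Write a film scan to a 16-bit RGB TIFF
#'
#' Inverse of [read_scan()]; the written file round-trips bit-identically.
#'
#' @param scan A `film_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  tiff::writeTIFF(scan$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Mean red-channel pixel value in a region of interest
#'
#' @param scan A `film_scan`.
#' @param roi Integer vector `c(row1, row2, col1, col2)` in pixel
#'   coordinates, inclusive; `NULL` uses the whole image.
#' @return The arithmetic mean of the red-channel samples in the ROI.
#' @export
red_channel_pv <- function(scan, roi = NULL) {
  stopifnot(inherits(scan, "film_scan"))
  d <- dim(scan$pixels)
  if (is.null(roi)) roi <- c(1L, d[1L], 1L, d[2L])
  if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4] ||
      roi[1] < 1L || roi[2] > d[1L] || roi[3] < 1L || roi[4] > d[2L])
    stop("roi error: region is empty or outside the image")
  mean(scan$pixels[roi[1]:roi[2], roi[3]:roi[4], 1L])
}

#' Net optical density from pixel values
#'
#' `netOD = log10(PV_unexposed / PV_exposed)`, which equals the difference of
#' the exposed and unexposed optical densities for any common OD reference,
#' so no scanner-maximum constant is needed.
#'
#' @param pv_exposed,pv_unexposed Positive pixel values (vectorized).
#' @return netOD, dimensionless.
#' @export
net_od <- function(pv_exposed, pv_unexposed) {
  if (any(pv_exposed <= 0) || any(pv_unexposed <= 0))
    stop("domain error: pixel values must be positive")
  if (any(pv_exposed > pv_unexposed))
    warning("exposed pixel value exceeds the unexposed one; negative netOD")
  log10(pv_unexposed / pv_exposed)
}

#' Fit the netOD-to-dose calibration polynomial
#'
#' Least-squares polynomial of `dose` on `netOD` (dose as a function of
#' netOD). A third-order polynomial is the standard choice for EBT3-type
#' film over 0-600 cGy.
#'
#' @param netod Net optical densities of the calibration films, distinct.
#' @param dose_cGy Delivered doses in cGy; should include a zero-dose film.
#' @param order Polynomial order (default 3).
#' @return A `calibration_curve`: coefficients in increasing power order,
#'   `netod_domain`, `r_squared`, `dose_levels_cGy`, and a `monotone` flag
#'   (a non-monotone fit over the sample domain is flagged with a warning
#'   but not fatal).
#' @export
fit_calibration <- function(netod, dose_cGy, order = 3L) {
  netod <- as.numeric(netod)
  dose_cGy <- as.numeric(dose_cGy)
  if (length(netod) != length(dose_cGy))
    stop("netod and dose_cGy must have the same length")
  if (length(netod) < order + 2L)
    stop(sprintf("fit error: need at least %d samples for an order-%d polynomial",
                 order + 2L, order))
  if (anyDuplicated(netod))
    stop("fit error: netOD values must be distinct")
  if (min(dose_cGy) > 0.02 * max(dose_cGy))
    warning("no zero-dose calibration sample; the curve is unanchored at netOD 0")
  fit <- stats::lm(dose_cGy ~ stats::poly(netod, degree = order, raw = TRUE))
  coefficients <- unname(stats::coef(fit))
  if (anyNA(coefficients))
    stop("fit error: rank-deficient calibration design")
  r2 <- .r_squared(dose_cGy, stats::fitted(fit))
  dom <- range(netod)
  grid <- seq(dom[1], dom[2], length.out = 512L)
  deriv <- .polyval(coefficients[-1L] * seq_len(order), grid)
  monotone <- all(deriv >= 0)
  if (!monotone)
    warning("calibration curve is not monotone increasing over the sample domain")
  structure(
    list(coefficients = coefficients, netod_domain = dom, r_squared = r2,
         dose_levels_cGy = sort(unique(dose_cGy)), monotone = monotone),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> order %d, netOD domain [%.4f, %.4f], R^2 = %.5f%s\n",
    length(x$coefficients) - 1L, x$netod_domain[1], x$netod_domain[2],
    x$r_squared, if (x$monotone) "" else " [non-monotone]"))
  cat("coefficients (increasing power):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

.polyval <- function(coefficients, x) {
  out <- numeric(length(x))
  for (k in rev(seq_along(coefficients))) out <- out * x + coefficients[k]
  out
}

#' Evaluate a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param netod netOD value(s).
#' @param warn_extrapolation Warn when evaluating outside the fitted domain
#'   (the value is still computed).
#' @return Dose(s) in cGy.
#' @export
predict_dose <- function(curve, netod, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (warn_extrapolation &&
      any(netod < curve$netod_domain[1] - 1e-12 |
          netod > curve$netod_domain[2] + 1e-12))
    warning("netOD outside the calibration domain; extrapolating the polynomial")
  .polyval(curve$coefficients, netod)
}

#' Invert a calibration curve (dose to netOD)
#'
#' Bisection on the monotone increasing branch starting at netOD 0.
#'
#' @param curve A `calibration_curve`.
#' @param dose_cGy Dose value(s), each within the invertible range.
#' @param upper Upper netOD bound for the search; default extends the fitted
#'   domain by 25%.
#' @param tol Bisection tolerance on netOD.
#' @return netOD value(s).
#' @export
invert_calibration <- function(curve, dose_cGy, upper = NULL, tol = 1e-6) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.null(upper)) upper <- 1.25 * curve$netod_domain[2]
  dmax <- predict_dose(curve, upper, warn_extrapolation = FALSE)
  if (any(dose_cGy < 0) || any(dose_cGy > dmax))
    stop(sprintf("range error: dose outside the invertible range [0, %.1f] cGy",
                 dmax))
  lo <- rep(0, length(dose_cGy))
  hi <- rep(upper, length(dose_cGy))
  for (i in seq_len(ceiling(log2(upper / tol)) + 1L)) {
    mid <- (lo + hi) / 2
    below <- predict_dose(curve, mid, warn_extrapolation = FALSE) < dose_cGy
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Convert a film scan to a dose map
#'
#' Per-pixel red-channel netOD against the unexposed pixel value, then
#' evaluation of the calibration polynomial.
#'
#' @param scan A `film_scan`.
#' @param pv_unexposed Unexposed-film red-channel pixel value (the OD
#'   reference).
#' @param curve A `calibration_curve`.
#' @return A numeric matrix of doses in cGy, same rows/cols as the scan.
#' @export
to_dose <- function(scan, pv_unexposed, curve) {
  stopifnot(inherits(scan, "film_scan"))
  pv <- pmax(scan$pixels[, , 1L], 1L)  # guard against dead pixels at 0
  netod <- suppressWarnings(net_od(pv, pv_unexposed))
  slack <- 0.02 * diff(curve$netod_domain)  # pixel noise straddles netOD 0
  if (any(netod > curve$netod_domain[2] + slack) ||
      any(netod < curve$netod_domain[1] - slack))
    warning("scan netOD range exceeds the calibration domain; extrapolating")
  dose <- .polyval(curve$coefficients, netod)
  dim(dose) <- dim(pv)
  dose
}

#' Construct a crossplane dose profile
#'
#' @param positions_mm Strictly increasing, uniformly spaced sampling
#'   positions along the crossplane axis, isocenter at 0.
#' @param dose_cGy Dose at each position. Negative values (possible after
#'   background subtraction) are allowed and retained.
#' @param background_cGy Matched-tail background level, `NA` before matching.
#' @param nominal_gap_mm The slit's set gap, `NA` if unknown.
#' @return A `dose_profile` object.
#' @export
dose_profile <- function(positions_mm, dose_cGy, background_cGy = NA_real_,
                         nominal_gap_mm = NA_real_) {
  positions_mm <- as.numeric(positions_mm)
  dose_cGy <- as.numeric(dose_cGy)
  if (length(positions_mm) != length(dose_cGy))
    stop("positions and doses must have the same length")
  if (length(positions_mm) >= 2L) {
    h <- diff(positions_mm)
    if (any(h <= 0)) stop("positions must be strictly increasing")
    if (max(h) - min(h) > 1e-6 * max(h))
      stop("positions must be uniformly spaced")
  }
  structure(list(positions_mm = positions_mm, dose_cGy = dose_cGy,
                 background_cGy = background_cGy,
                 nominal_gap_mm = nominal_gap_mm),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf(
    "<dose_profile> %d samples over [%.1f, %.1f] mm, peak %.1f cGy%s%s\n",
    length(x$positions_mm), min(x$positions_mm), max(x$positions_mm),
    max(x$dose_cGy),
    if (is.na(x$nominal_gap_mm)) "" else sprintf(", nominal gap %g mm",
                                                 x$nominal_gap_mm),
    if (is.na(x$background_cGy)) "" else sprintf(", background %.2f cGy",
                                                 x$background_cGy)))
  invisible(x)
}

#' Extract the crossplane dose profile from a dose map
#'
#' Column-wise mean over a band of rows centered on the slit's long axis
#' (the middle row). Positions are converted to mm with `25.4/dpi` per pixel
#' and the origin is placed at the dose-weighted center of the slit, taken
#' over samples at or above half of the maximum dose (films carry no
#' coordinate registration, and the half-maximum restriction keeps the
#' centroid insensitive to the background).
#'
#' @param dose_map Dose matrix from [to_dose()].
#' @param band_halfwidth_px Half-width of the averaging band in rows;
#'   0 uses the single central row.
#' @param dpi Scan resolution.
#' @param nominal_gap_mm Optional slit gap recorded in the result.
#' @return A [dose_profile()].
#' @export
extract_profile <- function(dose_map, band_halfwidth_px = 10L, dpi = 72,
                            nominal_gap_mm = NA_real_) {
  if (!is.matrix(dose_map)) stop("dose_map must be a matrix")
  mid <- (nrow(dose_map) + 1L) %/% 2L
  rows <- (mid - band_halfwidth_px):(mid + band_halfwidth_px)
  if (min(rows) < 1L || max(rows) > nrow(dose_map))
    stop("roi error: averaging band extends outside the image")
  prof <- colMeans(dose_map[rows, , drop = FALSE])
  h <- 25.4 / dpi
  x <- (seq_along(prof) - 1) * h
  core <- prof >= max(prof) / 2
  x0 <- sum(x[core] * prof[core]) / sum(prof[core])
  dose_profile(x - x0, prof, nominal_gap_mm = nominal_gap_mm)
}

#' Match the background tail of a profile to a common level
#'
#' The background of each film (transmission plus scanner/film response) is
#' estimated as the mean dose over two symmetric windows far from the slit
#' and the whole profile is shifted so the tails sit at a common configured
#' level. This removes the per-film dose-response offset before widths and
#' integrals are compared across films.
#'
#' @param profile A [dose_profile()].
#' @param tail_window_mm `c(start, end)`: the window `start <= |x| <= end` on
#'   both sides, in mm from the profile center. Must lie outside the
#'   cross-field region.
#' @param target_cGy Common tail level after matching (default 0).
#' @return The shifted [dose_profile()] with `background_cGy` set to the
#'   estimated level.
#' @export
match_background_tail <- function(profile, tail_window_mm = c(85, 105),
                                  target_cGy = 0) {
  stopifnot(inherits(profile, "dose_profile"))
  if (length(tail_window_mm) != 2L || tail_window_mm[1] >= tail_window_mm[2])
    stop("tail_window_mm must be c(start, end) with start < end")
  x <- profile$positions_mm
  idx <- abs(x) >= tail_window_mm[1] & abs(x) <= tail_window_mm[2]
  if (!any(idx & x < 0) || !any(idx & x > 0))
    stop("window error: tail window has no samples on both sides of the slit")
  tail_dose <- profile$dose_cGy[idx]
  med <- stats::median(tail_dose)
  peak <- max(profile$dose_cGy)
  if (med > 0.25 * peak ||
      any(tail_dose > 2 * max(med, 0) + 0.05 * peak))
    stop("window error: tail window overlaps the slit dose region")
  bg <- mean(tail_dose)
  dose_profile(x, profile$dose_cGy - bg + target_cGy,
               background_cGy = bg,
               nominal_gap_mm = profile$nominal_gap_mm)
}

#' Cross-field dose width of a background-matched profile
#'
#' Width of the contiguous region around the peak where the net dose is at
#' least `threshold_fraction` of the net peak. With the default threshold of
#' 0.005 this captures the full measurable dose extent of the slit. An
#' optional rounding grid reports the width to the nearest multiple of
#' `rounding_mm`.
#'
#' @param profile A background-matched [dose_profile()].
#' @param threshold_fraction Fraction of the net peak, in (0, 1).
#' @param rounding_mm Optional rounding grid in mm (e.g. 10); `NULL` for no
#'   rounding.
#' @return The width in mm.
#' @export
cross_field_width <- function(profile, threshold_fraction = 0.005,
                              rounding_mm = NULL) {
  stopifnot(inherits(profile, "dose_profile"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  net <- profile$dose_cGy
  peak <- max(net)
  if (peak <= 0) stop("empty-field error: net peak is not positive")
  thr <- threshold_fraction * peak
  ipk <- which.max(net)
  lo <- ipk
  while (lo > 1L && net[lo - 1L] >= thr) lo <- lo - 1L
  hi <- ipk
  while (hi < length(net) && net[hi + 1L] >= thr) hi <- hi + 1L
  width <- profile$positions_mm[hi] - profile$positions_mm[lo]
  if (!is.null(rounding_mm)) width <- round(width / rounding_mm) * rounding_mm
  width
}

#' Integral dose of a profile
#'
#' Trapezoidal integral of the (background-matched) dose over the full
#' recorded extent.
#'
#' @param profile A [dose_profile()].
#' @return Integral dose in cGy mm.
#' @export
integral_dose <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  x <- profile$positions_mm
  y <- profile$dose_cGy
  if (length(x) < 2L)
    stop("insufficient data: at least 2 samples are needed for the integral")
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Derive the DLG from film integral doses
#'
#' The integral dose of each background-matched slit profile is regressed
#' against the nominal gap width, exactly as in the chamber method; the DLG
#' is the absolute gap-axis intercept.
#'
#' @param gap_mm Nominal gap widths, at least 3.
#' @param integral_cGy_mm Integral doses from [integral_dose()].
#' @return A `dlg_estimate` tagged `"film"`.
#' @export
derive_dlg_film <- function(gap_mm, integral_cGy_mm) {
  fit_dlg(gap_mm, integral_cGy_mm, method_tag = "film")
}
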