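#' dlgcal: dosimetric leaf gap determination for rounded leaf-end MLCs
#'
#' The dosimetric leaf gap (DLG) is the effective widening of an MLC leaf-pair
#' gap caused by x-ray transmission through rounded leaf tips. It is derived
#' by sweeping a fixed gap across an ionization chamber at constant speed,
#' correcting each integral reading for leaf transmission, and extrapolating
#' the corrected readings linearly to their gap-axis intercept. The
#' transmission correction can use either the nominal (geometric) gap width or
#' the cross-field dose width measured from film, which accounts for the full
#' spatial extent of the slit dose distribution.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a sweeping-gap reading series
#'
#' A series of integral ionization readings, one per nominal gap width, taken
#' with the gap swept across the detector at constant speed for a single
#' beam/depth condition.
#'
#' @param condition_label Text tag for the beam condition (e.g. `"6MV"`).
#' @param depth_mm Measurement depth in mm (bookkeeping only; it does not
#'   enter the calculation).
#' @param gap_mm Numeric vector of nominal gap widths in mm, strictly
#'   increasing, all positive and smaller than `sweep_range_mm`.
#' @param reading Numeric vector of chamber readings, one per gap, all
#'   positive, in any single consistent unit.
#' @param sweep_range_mm Total leaf travel of the sweep in mm (default 120,
#'   i.e. -60 mm to +60 mm).
#' @return An object of class `gap_series`.
#' @export
gap_series <- function(condition_label, depth_mm, gap_mm, reading,
                       sweep_range_mm = 120) {
  gap_mm <- as.numeric(gap_mm)
  reading <- as.numeric(reading)
  if (length(gap_mm) != length(reading))
    stop("gap_mm and reading must have the same length")
  if (length(gap_mm) < 3L)
    stop("a gap series needs at least 3 entries (a line plus one degree of freedom)")
  if (any(!is.finite(gap_mm)) || any(!is.finite(reading)))
    stop("gap widths and readings must be finite")
  if (any(gap_mm <= 0))
    stop("all nominal gap widths must be strictly positive")
  if (any(diff(gap_mm) <= 0))
    stop("nominal gap widths must be strictly increasing")
  if (!is.numeric(sweep_range_mm) || length(sweep_range_mm) != 1L ||
      sweep_range_mm <= 0)
    stop("sweep_range_mm must be a single positive number")
  if (any(gap_mm >= sweep_range_mm))
    stop("all nominal gap widths must be smaller than the sweep range")
  if (any(reading <= 0))
    stop("all readings must be positive")
  structure(
    list(
      condition_label = as.character(condition_label),
      depth_mm = as.numeric(depth_mm),
      sweep_range_mm = as.numeric(sweep_range_mm),
      entries = data.frame(gap_nominal_mm = gap_mm, reading = reading)
    ),
    class = "gap_series"
  )
}

#' @export
print.gap_series <- function(x, ...) {
  cat(sprintf("<gap_series> %s, depth %g mm, sweep range %g mm, %d gaps\n",
              x$condition_label, x$depth_mm, x$sweep_range_mm,
              nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Average MLC leaf transmission from bank readings
#'
#' The transmission fraction is the mean of the two fully-closed bank
#' readings divided by the open-field reading taken under identical delivery.
#'
#' @param reading_bank_a,reading_bank_b Chamber readings with the detector
#'   fully shielded by MLC bank A and bank B respectively.
#' @param reading_open Open-field reference reading, same units and delivery.
#' @return An object of class `transmission_result` with the three readings
#'   echoed and the derived `transmission_fraction`.
#' @export
compute_transmission <- function(reading_bank_a, reading_bank_b, reading_open) {
  if (!is.numeric(reading_open) || length(reading_open) != 1L ||
      !is.finite(reading_open) || reading_open <= 0)
    stop("invalid reference: the open-field reading must be a single positive number")
  for (r in list(a = reading_bank_a, b = reading_bank_b)) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
      stop("bank readings must be single non-negative numbers")
  }
  if (reading_bank_a >= reading_open || reading_bank_b >= reading_open)
    stop("implausible transmission: a bank reading is not smaller than the open reading")
  fraction <- ((reading_bank_a + reading_bank_b) / 2) / reading_open
  structure(
    list(
      reading_bank_a = reading_bank_a,
      reading_bank_b = reading_bank_b,
      reading_open = reading_open,
      transmission_fraction = fraction
    ),
    class = "transmission_result"
  )
}

#' @export
print.transmission_result <- function(x, ...) {
  cat(sprintf(
    "<transmission_result> banks %g / %g, open %g, transmission %.4f (%.2f%%)\n",
    x$reading_bank_a, x$reading_bank_b, x$reading_open,
    x$transmission_fraction, 100 * x$transmission_fraction))
  invisible(x)
}

#' Transmission contribution to a sweeping-gap reading
#'
#' During a sweep of total travel `sweep_range_mm`, the detector is shielded
#' by the leaves for the fraction of the travel not spanned by the gap, so
#' the transmission contribution to the integral reading is
#' `R_T * (1 - g / sweep_range)`.
#'
#' @param transmission_fraction Leaf transmission fraction `R_T` (or the
#'   transmission reading, if readings are not normalized; the result is then
#'   in reading units).
#' @param gap_width_mm Gap width `g` used in the correction, in mm. Under the
#'   nominal convention this is the set gap; under the cross-field convention
#'   it is the cross-field dose width.
#' @param sweep_range_mm Total sweep travel in mm (default 120).
#' @return The correction, linear and decreasing in `gap_width_mm`.
#' @export
transmission_correction <- function(transmission_fraction, gap_width_mm,
                                    sweep_range_mm = 120) {
  if (!is.numeric(sweep_range_mm) || length(sweep_range_mm) != 1L ||
      sweep_range_mm <= 0)
    stop("sweep_range_mm must be a single positive number")
  if (any(gap_width_mm < 0))
    stop("gap widths must be non-negative")
  if (any(gap_width_mm > sweep_range_mm))
    stop("out of range: gap width exceeds the sweep range (the correction would go negative)")
  transmission_fraction * (1 - gap_width_mm / sweep_range_mm)
}

#' Subtract the transmission contribution from a gap reading
#'
#' `reading` and `correction` must share one unit (both raw readings or both
#' normalized to the same open-field reference); this cannot be detected
#' numerically and is a documented contract. Non-positive corrected readings
#' are kept (they remain informative for diagnostic plots) but flagged with a
#' warning.
#'
#' @param reading Initial sweeping-gap reading `Rg`.
#' @param correction Transmission contribution from
#'   [transmission_correction()].
#' @return `reading - correction`.
#' @export
corrected_reading <- function(reading, correction) {
  out <- reading - correction
  if (any(out <= 0))
    warning("non-positive corrected reading(s); kept in the output")
  out
}

## R^2 on residuals without summary.lm (which warns on exact fits).
.r_squared <- function(y, fitted) {
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

#' Fit the DLG regression line
#'
#' Ordinary unweighted least squares of corrected readings against the
#' nominal gap width. The DLG is the absolute value of the gap-axis
#' intercept, `|-c/m|` for the fitted line `m*g + c`.
#'
#' @param gap_mm Nominal gap widths (abscissa), at least 3 distinct values.
#' @param corrected Corrected readings, same length.
#' @param method_tag Label stored in the result: `"nominal"`, `"crossfield"`
#'   or `"film"`.
#' @return An object of class `dlg_estimate` with fields `slope`,
#'   `intercept`, `dlg_mm`, `r_squared`, `method_tag`, `n_points`.
#' @export
fit_dlg <- function(gap_mm, corrected, method_tag = "nominal") {
  gap_mm <- as.numeric(gap_mm)
  corrected <- as.numeric(corrected)
  if (length(gap_mm) != length(corrected))
    stop("gap_mm and corrected must have the same length")
  if (length(gap_mm) < 3L)
    stop("insufficient data: at least 3 points are required for the DLG fit")
  if (anyDuplicated(gap_mm))
    stop("gap values must be distinct")
  fit <- stats::lm(corrected ~ gap_mm)
  cf <- stats::coef(fit)
  intercept <- unname(cf[1L])
  slope <- unname(cf[2L])
  if (!is.finite(slope) || slope <= 0)
    stop(sprintf("degenerate fit: slope %g is not positive", slope))
  dlg_mm <- abs(-intercept / slope)
  if (!is.finite(dlg_mm))
    stop("degenerate fit: non-finite DLG")
  r2 <- .r_squared(corrected, stats::fitted(fit))
  structure(
    list(
      slope = slope,
      intercept = intercept,
      dlg_mm = dlg_mm,
      r_squared = r2,
      method_tag = as.character(method_tag),
      n_points = length(gap_mm)
    ),
    class = "dlg_estimate"
  )
}

#' @export
print.dlg_estimate <- function(x, ...) {
  cat(sprintf(
    "<dlg_estimate> method %s: DLG = %.3f mm (slope %.5g, intercept %.5g, R^2 %.5f, n = %d)\n",
    x$method_tag, x$dlg_mm, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Construct a nominal-to-dosimetric gap width table
#'
#' Maps each nominal gap width to the cross-field dose width measured from a
#' static slit film, for use in the transmission correction.
#'
#' @param g_nominal_mm Nominal gap widths, strictly increasing.
#' @param g_dose_mm Cross-field dose widths, strictly increasing and never
#'   smaller than the nominal width.
#' @return A data frame of class `gap_width_table`.
#' @seealso [default_gap_width_table()]
#' @export
gap_width_table <- function(g_nominal_mm, g_dose_mm) {
  g_nominal_mm <- as.numeric(g_nominal_mm)
  g_dose_mm <- as.numeric(g_dose_mm)
  if (length(g_nominal_mm) != length(g_dose_mm))
    stop("the two columns must have the same length")
  if (any(diff(g_nominal_mm) <= 0) || any(diff(g_dose_mm) <= 0))
    stop("both columns must be strictly increasing")
  if (any(g_dose_mm < g_nominal_mm))
    stop("the cross-field dose width cannot be smaller than the nominal gap width")
  structure(
    data.frame(g_nominal_mm = g_nominal_mm, g_dose_mm = g_dose_mm),
    class = c("gap_width_table", "data.frame")
  )
}

#' The measured cross-field dose width table
#'
#' Cross-field dose widths of static slit fields for nominal gaps of
#' 2, 4, 6, 10, 14, 16 and 20 mm are 30, 40, 50, 60, 70, 80 and 90 mm: the
#' dose extent of a slit is far larger than its geometric width because of
#' penumbra, phantom scatter and leaf-tip transmission. This mapping was
#' found to be essentially independent of beam energy.
#'
#' @return A `gap_width_table`.
#' @export
default_gap_width_table <- function() {
  gap_width_table(c(2, 4, 6, 10, 14, 16, 20),
                  c(30, 40, 50, 60, 70, 80, 90))
}

#' Look up the cross-field dose width of a nominal gap
#'
#' Unlisted gaps are an error by default: the table is a measurement, and
#' silent interpolation would hide a missing film.
#'
#' @param table A [gap_width_table()].
#' @param g_nominal_mm Nominal gap width(s) to look up.
#' @param interpolate If `TRUE`, linearly interpolate unlisted gaps inside
#'   the table range instead of failing.
#' @return Cross-field dose width(s) in mm.
#' @export
lookup_gap_width <- function(table, g_nominal_mm, interpolate = FALSE) {
  stopifnot(inherits(table, "gap_width_table"))
  idx <- match(g_nominal_mm, table$g_nominal_mm)
  if (anyNA(idx)) {
    missing <- g_nominal_mm[is.na(idx)]
    if (!interpolate)
      stop(sprintf("gap width(s) not in the table: %s mm",
                   paste(missing, collapse = ", ")))
    return(stats::approx(table$g_nominal_mm, table$g_dose_mm,
                         xout = g_nominal_mm, rule = 1)$y)
  }
  table$g_dose_mm[idx]
}

## Shared worker for both derivation conventions. Readings are normalized to
## the open-field reading of the transmission measurement so that Eq.-style
## corrections (a fraction) and the gap readings share one unit; the DLG is
## invariant under this common scaling.
derive_dlg <- function(series, transmission, gap_for_correction, method_tag) {
  stopifnot(inherits(series, "gap_series"),
            inherits(transmission, "transmission_result"))
  g <- series$entries$gap_nominal_mm
  r_norm <- series$entries$reading / transmission$reading_open
  corr <- transmission_correction(transmission$transmission_fraction,
                                  gap_for_correction,
                                  series$sweep_range_mm)
  fit_dlg(g, corrected_reading(r_norm, corr), method_tag = method_tag)
}

#' Derive the DLG with the nominal-gap transmission correction
#'
#' The manufacturer's convention: the transmission correction for each
#' reading uses the geometric (nominal) gap width.
#'
#' @param series A [gap_series()].
#' @param transmission A [compute_transmission()] result taken under the same
#'   condition, with readings in the same units as the series.
#' @return A `dlg_estimate` tagged `"nominal"`.
#' @export
derive_dlg_nominal <- function(series, transmission) {
  derive_dlg(series, transmission,
             gap_for_correction = series$entries$gap_nominal_mm,
             method_tag = "nominal")
}

#' Derive the DLG with the cross-field dose width correction
#'
#' The transmission correction for each reading uses the cross-field dose
#' width looked up from `table`, because the leaves shield the detector only
#' outside the full dose extent of the slit, not outside its geometric
#' width. The regression abscissa remains the nominal gap width, so the DLG
#' stays a leaf-position offset in nominal coordinates.
#'
#' @param series A [gap_series()].
#' @param transmission A [compute_transmission()] result for the condition.
#' @param table A [gap_width_table()]; every gap in the series must be
#'   listed.
#' @return A `dlg_estimate` tagged `"crossfield"`.
#' @export
derive_dlg_crossfield <- function(series, transmission,
                                  table = default_gap_width_table()) {
  g_dose <- lookup_gap_width(table, series$entries$gap_nominal_mm)
  derive_dlg(series, transmission,
             gap_for_correction = g_dose,
             method_tag = "crossfield")
}

#' Derive nominal and cross-field DLGs for a batch of conditions
#'
#' @param conditions A list; each element is a list with components `series`
#'   (a [gap_series()]) and `transmission` (a [compute_transmission()]
#'   result).
#' @param table A [gap_width_table()] for the cross-field method.
#' @return A data frame with one row per condition and method, ordered by
#'   condition label then depth, with columns `condition`, `depth_mm`,
#'   `method`, `slope`, `intercept`, `dlg_mm`, `r_squared`, `n_points` and
#'   `error` (NA on success; per-condition failures do not stop the batch).
#' @export
batch_derive <- function(conditions, table = default_gap_width_table()) {
  if (!is.list(conditions) || length(conditions) == 0L)
    stop("conditions must be a non-empty list")
  rows <- list()
  for (cond in conditions) {
    s <- cond$series
    for (method in c("nominal", "crossfield")) {
      est <- tryCatch(
        if (method == "nominal") derive_dlg_nominal(s, cond$transmission)
        else derive_dlg_crossfield(s, cond$transmission, table),
        error = function(e) e
      )
      rows[[length(rows) + 1L]] <- if (inherits(est, "error")) {
        data.frame(condition = s$condition_label, depth_mm = s$depth_mm,
                   method = method, slope = NA_real_, intercept = NA_real_,
                   dlg_mm = NA_real_, r_squared = NA_real_,
                   n_points = nrow(s$entries), error = conditionMessage(est))
      } else {
        data.frame(condition = s$condition_label, depth_mm = s$depth_mm,
                   method = method, slope = est$slope,
                   intercept = est$intercept, dlg_mm = est$dlg_mm,
                   r_squared = est$r_squared, n_points = est$n_points,
                   error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$depth_mm, out$method), ]
  rownames(out) <- NULL
  out
}
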