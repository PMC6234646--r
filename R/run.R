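## Reproducible end-to-end runs over the file-based interfaces. These are the
## functions the command-line front end (exec/dlgcal) wraps; calling them
## directly gives bit-identical results.

.estimate_as_list <- function(est) {
  list(method_tag = est$method_tag, slope = est$slope,
       intercept = est$intercept, dlg_mm = est$dlg_mm,
       r_squared = est$r_squared, n_points = est$n_points)
}

#' Run the sweeping-gap DLG pipeline from CSV inputs
#'
#' Reads per-condition chamber and transmission CSVs, derives the DLG under
#' the requested convention(s) and returns (optionally writes) a JSON-ready
#' report.
#'
#' @param chamber_csv Chamber readings CSV (see [read_gap_readings()]).
#' @param transmission_csv Transmission CSV (see [read_transmission()]).
#' @param method `"nominal"`, `"crossfield"` or `"both"`.
#' @param gap_table A [gap_width_table()], a CSV path, or `NULL` for the
#'   measured default table.
#' @param sweep_range_mm Sweep travel (default 120).
#' @param out Optional JSON report path.
#' @return The report list, invisibly if `out` is given.
#' @export
run_sweep <- function(chamber_csv, transmission_csv,
                      method = c("both", "nominal", "crossfield"),
                      gap_table = NULL, sweep_range_mm = 120, out = NULL) {
  method <- match.arg(method)
  series <- read_gap_readings(chamber_csv, sweep_range_mm = sweep_range_mm)
  trans <- read_transmission(transmission_csv)
  table <- if (is.null(gap_table)) default_gap_width_table()
           else if (is.character(gap_table)) read_gap_width_table(gap_table)
           else gap_table
  conditions <- list()
  for (key in names(series)) {
    if (!key %in% names(trans))
      stop(sprintf("no transmission reading for condition %s", key))
    cond <- list(series = series[[key]], transmission = trans[[key]])
    ests <- list()
    if (method %in% c("both", "nominal"))
      ests$nominal <- .estimate_as_list(
        derive_dlg_nominal(cond$series, cond$transmission))
    if (method %in% c("both", "crossfield"))
      ests$crossfield <- .estimate_as_list(
        derive_dlg_crossfield(cond$series, cond$transmission, table))
    conditions[[key]] <- list(
      condition = cond$series$condition_label,
      depth_mm = cond$series$depth_mm,
      transmission_fraction = cond$transmission$transmission_fraction,
      inputs = list(gap_mm = cond$series$entries$gap_nominal_mm,
                    reading = cond$series$entries$reading),
      estimates = ests)
  }
  report <- c(.report_header(list(mode = "sweep", method = method,
                                  chamber_csv = chamber_csv,
                                  transmission_csv = transmission_csv,
                                  sweep_range_mm = sweep_range_mm)),
              list(gap_width_table = as.data.frame(unclass(table)),
                   conditions = conditions))
  if (!is.null(out)) {
    write_report(report, out)
    return(invisible(report))
  }
  report
}

#' Fit a film calibration curve from CSV samples
#'
#' @param calibration_csv Calibration CSV (see [read_calibration_samples()]).
#' @param order Polynomial order (default 3).
#' @param out Optional JSON report path.
#' @return The report list with the fitted curve; invisibly if `out` is
#'   given. The curve object itself is in `$curve`.
#' @export
run_calibrate <- function(calibration_csv, order = 3L, out = NULL) {
  samples <- read_calibration_samples(calibration_csv)
  netod <- net_od(samples$pv_exposed, samples$pv_unexposed)
  curve <- fit_calibration(netod, samples$dose_cGy, order = order)
  report <- c(.report_header(list(mode = "calibrate",
                                  calibration_csv = calibration_csv,
                                  order = order)),
              list(calibration = list(
                coefficients = curve$coefficients,
                netod_domain = curve$netod_domain,
                r_squared = curve$r_squared,
                dose_levels_cGy = curve$dose_levels_cGy,
                monotone = curve$monotone)))
  report$curve <- curve
  if (!is.null(out)) {
    write_report(report[names(report) != "curve"], out)
    return(invisible(report))
  }
  report
}

#' Run the film DLG pipeline
#'
#' Fits the netOD-to-dose calibration, converts each manifest scan to dose,
#' extracts and background-matches the crossplane profile, measures the
#' cross-field dose width and integral dose per gap, and derives the
#' film DLG from the integrals.
#'
#' @param calibration_csv Calibration CSV.
#' @param manifest_csv Manifest CSV with columns `gap_mm,scan_path`.
#' @param dpi Scan resolution (default 72).
#' @param band_halfwidth_px Profile averaging band half-width in rows.
#' @param tail_window_mm Background tail window, `c(start, end)` in mm.
#' @param threshold_fraction Width threshold as a fraction of the net peak.
#' @param rounding_mm Width rounding grid; `NULL` disables rounding.
#' @param condition_label Condition tag recorded in the report.
#' @param out Optional JSON report path.
#' @return The report list; invisibly if `out` is given.
#' @export
run_film <- function(calibration_csv, manifest_csv, dpi = 72,
                     band_halfwidth_px = 10L, tail_window_mm = c(85, 105),
                     threshold_fraction = 0.005, rounding_mm = 10,
                     condition_label = NA_character_, out = NULL) {
  cal <- run_calibrate(calibration_csv)
  curve <- cal$curve
  samples <- read_calibration_samples(calibration_csv)
  pv_unexposed <- mean(samples$pv_unexposed)
  manifest <- read_film_manifest(manifest_csv)
  manifest <- manifest[order(manifest$gap_mm), ]

  per_gap <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$scan_path[i]
    if (!file.exists(p))
      stop(sprintf("manifest references a missing scan file: %s", p))
    scan <- read_scan(p, dpi = dpi)
    dose_map <- to_dose(scan, pv_unexposed, curve)
    prof <- extract_profile(dose_map, band_halfwidth_px = band_halfwidth_px,
                            dpi = dpi, nominal_gap_mm = manifest$gap_mm[i])
    prof <- match_background_tail(prof, tail_window_mm = tail_window_mm)
    per_gap[[i]] <- list(
      gap_mm = manifest$gap_mm[i],
      scan_path = p,
      background_cGy = prof$background_cGy,
      width_mm = cross_field_width(prof, threshold_fraction),
      width_rounded_mm = cross_field_width(prof, threshold_fraction,
                                           rounding_mm = rounding_mm),
      integral_cGy_mm = integral_dose(prof))
  }
  gaps <- vapply(per_gap, `[[`, 0, "gap_mm")
  integrals <- vapply(per_gap, `[[`, 0, "integral_cGy_mm")
  widths_rounded <- vapply(per_gap, `[[`, 0, "width_rounded_mm")
  est <- derive_dlg_film(gaps, integrals)

  report <- c(.report_header(list(mode = "film",
                                  calibration_csv = calibration_csv,
                                  manifest_csv = manifest_csv, dpi = dpi,
                                  band_halfwidth_px = band_halfwidth_px,
                                  tail_window_mm = tail_window_mm,
                                  threshold_fraction = threshold_fraction,
                                  rounding_mm = rounding_mm,
                                  condition_label = condition_label)),
              list(calibration = cal$calibration,
                   films = per_gap,
                   measured_gap_width_table = data.frame(
                     g_nominal_mm = gaps, g_dose_mm = widths_rounded),
                   estimate = .estimate_as_list(est)))
  if (!is.null(out)) {
    write_report(report, out)
    return(invisible(report))
  }
  report
}

#' Write a simulated dataset to disk in the pipeline input formats
#'
#' Serializes a [make_dataset()] result as the CSVs, TIFF scans and manifest
#' that [run_sweep()] and [run_film()] read, plus a truth sidecar JSON with
#' the ground-truth dosimetric gap, the model parameters and the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed passed to [make_dataset()].
#' @param dataset Optional pre-built `simulated_dataset`; when given, `seed`
#'   is ignored.
#' @param ... Further arguments to [make_dataset()].
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, dataset = NULL, ...) {
  if (is.null(dataset)) dataset <- make_dataset(seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop(sprintf("output directory is not writable: %s", out_dir))
  s <- dataset$chamber_series
  full <- function(x) sprintf("%.17g", x)  # readings survive the round trip
  chamber <- file.path(out_dir, "chamber.csv")
  utils::write.csv(
    data.frame(condition = s$condition_label, depth_mm = s$depth_mm,
               gap_mm = s$entries$gap_nominal_mm,
               reading = full(s$entries$reading)),
    chamber, row.names = FALSE, quote = FALSE)
  tr <- dataset$transmission
  transmission <- file.path(out_dir, "transmission.csv")
  utils::write.csv(
    data.frame(condition = s$condition_label, depth_mm = s$depth_mm,
               bank_a = full(tr$reading_bank_a),
               bank_b = full(tr$reading_bank_b),
               open = full(tr$reading_open)),
    transmission, row.names = FALSE, quote = FALSE)
  calibration <- file.path(out_dir, "calibration.csv")
  utils::write.csv(dataset$calibration, calibration, row.names = FALSE)
  scan_files <- character(0)
  for (i in seq_along(dataset$gaps)) {
    f <- file.path(out_dir, sprintf("scan_gap_%02d.tif", dataset$gaps[i]))
    write_scan(dataset$film_scans[[i]], f)
    scan_files <- c(scan_files, f)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(data.frame(gap_mm = dataset$gaps,
                              scan_path = basename(scan_files)),
                   manifest, row.names = FALSE)
  truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(dlg_true_mm = dataset$dlg_true_mm,
         transmission_fraction = dataset$transmission$transmission_fraction,
         model = unclass(dataset$model), seed = dataset$seed,
         gaps = dataset$gaps),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(chamber = chamber, transmission = transmission,
                 calibration = calibration, manifest = manifest,
                 scans = scan_files, truth = truth))
}
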