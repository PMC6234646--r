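## Plain-text interchange formats: chamber readings, transmission readings,
## gap-width tables, calibration samples, film manifests, JSON reports.

.read_csv_checked <- function(path, required_cols, what) {
  if (!file.exists(path))
    stop(sprintf("parse error: %s file not found: %s", what, path))
  df <- tryCatch(utils::read.csv(path, strip.white = TRUE),
                 error = function(e)
                   stop(sprintf("parse error in %s (%s): %s", path, what,
                                conditionMessage(e))))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("parse error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  for (col in setdiff(required_cols, c("condition", "scan_path"))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("parse error in %s, line %d: column %s is not numeric",
                   path, bad + 1L, col))
    }
  }
  df
}

#' Read sweeping-gap chamber readings from CSV
#'
#' Expected columns: `condition,depth_mm,gap_mm,reading`, one row per gap,
#' with a header row.
#'
#' @param path CSV path.
#' @param sweep_range_mm Sweep travel assigned to every series (default 120).
#' @return A named list of [gap_series()], one per condition/depth, named
#'   `"<condition>@<depth_mm>"`.
#' @export
read_gap_readings <- function(path, sweep_range_mm = 120) {
  df <- .read_csv_checked(path, c("condition", "depth_mm", "gap_mm", "reading"),
                          "chamber readings")
  key <- paste0(df$condition, "@", df$depth_mm)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$gap_mm), ]
    gap_series(d$condition[1L], d$depth_mm[1L], d$gap_mm, d$reading,
               sweep_range_mm = sweep_range_mm)
  })
  out[unique(key)]
}

#' Read MLC transmission readings from CSV
#'
#' Expected columns: `condition,depth_mm,bank_a,bank_b,open`.
#'
#' @param path CSV path.
#' @return A named list of `transmission_result`, named
#'   `"<condition>@<depth_mm>"`.
#' @export
read_transmission <- function(path) {
  df <- .read_csv_checked(path, c("condition", "depth_mm", "bank_a", "bank_b",
                                  "open"), "transmission readings")
  key <- paste0(df$condition, "@", df$depth_mm)
  out <- lapply(split(df, key), function(d)
    compute_transmission(d$bank_a[1L], d$bank_b[1L], d$open[1L]))
  out[unique(key)]
}

#' Read a gap-width table from CSV
#'
#' Expected columns: `g_nominal_mm,g_dose_mm`.
#'
#' @param path CSV path.
#' @return A [gap_width_table()].
#' @export
read_gap_width_table <- function(path) {
  df <- .read_csv_checked(path, c("g_nominal_mm", "g_dose_mm"),
                          "gap-width table")
  df <- df[order(df$g_nominal_mm), ]
  gap_width_table(df$g_nominal_mm, df$g_dose_mm)
}

#' Read film calibration samples from CSV
#'
#' Expected columns: `dose_cGy,pv_exposed,pv_unexposed`, one row per dose
#' level.
#'
#' @param path CSV path.
#' @return The data frame.
#' @export
read_calibration_samples <- function(path) {
  .read_csv_checked(path, c("dose_cGy", "pv_exposed", "pv_unexposed"),
                    "calibration samples")
}

#' Read a film manifest from CSV
#'
#' Expected columns: `gap_mm,scan_path`. Relative scan paths are resolved
#' against the manifest's directory.
#'
#' @param path CSV path.
#' @return Data frame with absolute `scan_path`.
#' @export
read_film_manifest <- function(path) {
  df <- .read_csv_checked(path, c("gap_mm", "scan_path"), "film manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", df$scan_path)
  df$scan_path[rel] <- file.path(dirname(path), df$scan_path[rel])
  df
}

#' Write a run report as JSON
#'
#' @param report A report list from one of the `run_*` pipelines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.report_header <- function(config) {
  list(package = "dlgcal",
       version = as.character(utils::packageVersion("dlgcal")),
       config = config)
}
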