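#' Parametric rounded leaf-tip model
#'
#' A geometric surrogate for an MLC bank with rounded leaf ends: a ray at
#' depth `d` behind the tip traverses the circular-tip chord
#' `min(leaf_thickness, 2*sqrt(R^2 - (R-d)^2))` of tungsten, attenuated
#' exponentially with `mu_per_mm`. The dose profile of a slit is the two-bank
#' fluence blurred by a Gaussian source-penumbra kernel plus a broad
#' exponential phantom-scatter tail.
#'
#' The defaults are frozen so that closed-leaf transmission equals 1.74%
#' (a typical measured 6 MV value for this MLC class) and so that the
#' f = 0.005 cross-field width rule with 10 mm rounding maps nominal gaps
#' 2, 4, 6, 10, 14, 16, 20 mm to dose widths 30, 40, 50, 60, 70, 80, 90 mm.
#'
#' @param tip_radius_mm Leaf-tip radius of curvature (default 80).
#' @param leaf_thickness_mm Full attenuating leaf thickness along the beam
#'   (default 60).
#' @param mu_per_mm Linear attenuation coefficient of the leaf material;
#'   default gives deep-leaf transmission `exp(-mu*thickness) = 0.0174`.
#' @param source_sigma_mm Gaussian penumbra width (default 1.5).
#' @param scatter_fraction Amplitude of the scatter tail relative to the
#'   primary component, in \[0, 0.2\] (default 0.095).
#' @param scatter_range_mm Decay length of the exponential scatter tail
#'   (default 18.5).
#' @param open_dose_cGy_per_MU Open-field primary output factor at the
#'   measurement point (default 0.9).
#' @return A `leafend_model` object.
#' @export
leafend_model <- function(tip_radius_mm = 80,
                          leaf_thickness_mm = 60,
                          mu_per_mm = log(1 / 0.0174) / 60,
                          source_sigma_mm = 1.5,
                          scatter_fraction = 0.095,
                          scatter_range_mm = 18.5,
                          open_dose_cGy_per_MU = 0.9) {
  for (v in list(tip_radius_mm, leaf_thickness_mm, mu_per_mm,
                 source_sigma_mm, scatter_range_mm, open_dose_cGy_per_MU)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all model lengths and coefficients must be single positive numbers")
  }
  if (scatter_fraction < 0 || scatter_fraction > 0.2)
    stop("scatter_fraction must lie in [0, 0.2]")
  transmission <- exp(-mu_per_mm * leaf_thickness_mm)
  if (transmission > 0.05)
    stop(sprintf("deep-leaf transmission %.3f exceeds 0.05; not a shielding leaf",
                 transmission))
  structure(
    list(tip_radius_mm = tip_radius_mm,
         leaf_thickness_mm = leaf_thickness_mm,
         mu_per_mm = mu_per_mm,
         source_sigma_mm = source_sigma_mm,
         scatter_fraction = scatter_fraction,
         scatter_range_mm = scatter_range_mm,
         open_dose_cGy_per_MU = open_dose_cGy_per_MU),
    class = "leafend_model"
  )
}

#' @export
print.leafend_model <- function(x, ...) {
  cat(sprintf(
    "<leafend_model> tip R %g mm, thickness %g mm, mu %.5f /mm (T = %.4f),\n  penumbra sigma %g mm, scatter %g @ %g mm, open dose %g cGy/MU\n",
    x$tip_radius_mm, x$leaf_thickness_mm, x$mu_per_mm, leaf_transmission(x),
    x$source_sigma_mm, x$scatter_fraction, x$scatter_range_mm,
    x$open_dose_cGy_per_MU))
  invisible(x)
}

#' Deep-leaf transmission of a model
#'
#' @param model A [leafend_model()].
#' @return `exp(-mu_per_mm * leaf_thickness_mm)`.
#' @export
leaf_transmission <- function(model) {
  exp(-model$mu_per_mm * model$leaf_thickness_mm)
}

#' Attenuation path length through a rounded leaf tip
#'
#' @param depth_from_tip_mm Signed depth behind the tip; negative is the open
#'   side (vectorized).
#' @param model A [leafend_model()].
#' @return Path length in mm: 0 on the open side, the circular chord capped
#'   at the leaf thickness inside the tip region, and the full thickness
#'   deeper than one tip radius. Continuous everywhere up to the chord cap.
#' @export
path_length <- function(depth_from_tip_mm, model) {
  R <- model$tip_radius_mm
  d <- depth_from_tip_mm
  out <- numeric(length(d))
  tip <- d > 0 & d <= R
  out[tip] <- pmin(model$leaf_thickness_mm, 2 * sqrt(R^2 - (R - d[tip])^2))
  out[d > R] <- model$leaf_thickness_mm
  out
}

#' Relative fluence across a static slit
#'
#' Bank tips sit at -gap/2 and +gap/2; the fluence at crossplane position x
#' is `exp(-mu * (path_A(x) + path_B(x)))`. The two banks attenuate on
#' disjoint sides except for very small gaps, where the tip shadows overlap
#' and the central fluence drops below 1.
#'
#' @param x_mm Crossplane position(s) in mm.
#' @param gap_mm Slit gap width, positive.
#' @param model A [leafend_model()].
#' @return Relative fluence in (0, 1].
#' @export
slit_fluence <- function(x_mm, gap_mm, model) {
  if (gap_mm <= 0) stop("gap_mm must be positive")
  d_a <- (-gap_mm / 2) - x_mm
  d_b <- x_mm - gap_mm / 2
  exp(-model$mu_per_mm * (path_length(d_a, model) + path_length(d_b, model)))
}

## Discrete kernels normalized to unit sum, so convolution preserves the
## discrete integral of the input.
.gauss_kernel <- function(sigma_mm, h_mm) {
  if (sigma_mm <= 0) return(1)
  n <- ceiling(6 * sigma_mm / h_mm)
  k <- stats::dnorm(seq(-n, n) * h_mm, sd = sigma_mm)
  k / sum(k)
}

.exp_kernel <- function(range_mm, h_mm) {
  if (range_mm <= 0) return(1)
  n <- ceiling(14 * range_mm / h_mm)
  k <- exp(-abs(seq(-n, n)) * h_mm / range_mm)
  k / sum(k)
}

## Same-size convolution (FFT) with edge-value padding (the far field is a
## constant transmission plateau, so edge padding is exact there).
.conv_same <- function(y, k) {
  if (length(k) == 1L) return(y * k)
  m <- (length(k) - 1L) / 2L
  yp <- c(rep(y[1L], m), y, rep(y[length(y)], m))
  n_full <- length(yp) + length(k) - 1L
  N <- stats::nextn(n_full)  # pad to a composite length; fft is O(N log N) there
  fy <- stats::fft(c(yp, numeric(N - length(yp))))
  fk <- stats::fft(c(k, numeric(N - length(k))))
  full <- Re(stats::fft(fy * fk, inverse = TRUE)) / N
  full[(2L * m + 1L):(2L * m + length(y))]
}

## Relative dose (per cGy/MU of open output) on a uniform grid. The fluence
## has a slope discontinuity at each tip edge, so the convolution is done on
## an internally refined subgrid and decimated back: at the requested
## sampling alone the discrete convolution acquires a small additive bias
## that would propagate into the DLG intercept.
.relative_dose <- function(x, gap_mm, model, refine = 1L) {
  h <- (x[2L] - x[1L]) / refine
  xf <- x[1L] + h * (seq_len((length(x) - 1L) * refine + 1L) - 1L)
  f <- slit_fluence(xf, gap_mm, model)
  p <- .conv_same(f, .gauss_kernel(model$source_sigma_mm, h)) +
    model$scatter_fraction * .conv_same(f, .exp_kernel(model$scatter_range_mm, h))
  p[seq(1L, length(xf), by = refine)]
}

#' Simulate the dose profile of a static slit field
#'
#' Fluence convolved with the unit-integral source-penumbra kernel, plus
#' `scatter_fraction` times the fluence convolved with the unit-integral
#' scatter kernel, scaled by the open dose and monitor units.
#'
#' @param gap_mm Nominal slit gap in mm.
#' @param MU Delivered monitor units (default 600).
#' @param model A [leafend_model()].
#' @param sampling_mm Grid spacing in mm; the default is the native pixel
#'   pitch of a 72 dpi scan, 25.4/72.
#' @param extent_mm Half-extent of the profile in mm (default 115).
#' @return A [dose_profile()] with the nominal gap recorded.
#' @export
simulate_dose_profile <- function(gap_mm, MU = 600, model = leafend_model(),
                                  sampling_mm = 25.4 / 72, extent_mm = 115) {
  if (sampling_mm <= 0) stop("sampling_mm must be positive")
  x <- seq(-extent_mm, extent_mm, by = sampling_mm)
  refine <- max(1L, ceiling(sampling_mm / 0.05))
  dose <- model$open_dose_cGy_per_MU * MU *
    .relative_dose(x, gap_mm, model, refine = refine)
  dose_profile(x, dose, nominal_gap_mm = gap_mm)
}

#' Ground-truth dosimetric gap extension of a model
#'
#' The integral of the net unconvolved fluence of a probe slit,
#' `(P - T) / (1 - T)`, minus the probe gap: the excess of the dosimetric
#' over the geometric field width contributed by the two leaf tips. The
#' blurring kernels integrate to one, so the convolved and unconvolved
#' definitions agree; the result is independent of the probe gap once the
#' two tip shadows no longer overlap (stable to < 0.02 mm over probe gaps
#' 6-20 mm for default-like models).
#'
#' @param model A [leafend_model()].
#' @param probe_gap_mm Probe slit width (default 10).
#' @param sampling_mm Integration step (default 0.01).
#' @return The dosimetric gap extension in mm.
#' @export
reference_dlg <- function(model, probe_gap_mm = 10, sampling_mm = 0.01) {
  Tt <- leaf_transmission(model)
  ext <- probe_gap_mm / 2 + model$tip_radius_mm + 5
  x <- seq(-ext, ext, by = sampling_mm)
  netP <- (slit_fluence(x, probe_gap_mm, model) - Tt) / (1 - Tt)
  sum((netP[-1L] + netP[-length(netP)]) / 2) * sampling_mm - probe_gap_mm
}

#' Simulate an integral sweeping-gap chamber reading
#'
#' The slit is swept at constant speed over leaf-pair center positions from
#' `-sweep_range_mm/2` to `+sweep_range_mm/2`; a point detector at isocenter
#' accumulates the dose. The reading is the trapezoidal integral of the
#' profile over the sweep window times `MU / sweep_range_mm`. In the
#' analytic limit this equals
#' `(MU * open_reading_per_MU / sweep) * ((1-T)(g + dlg_true) + T * sweep)`,
#' where the open reading includes the scatter component.
#'
#' @param gap_mm Nominal gap width, smaller than the sweep range.
#' @param model A [leafend_model()].
#' @param sweep_range_mm Total sweep travel (default 120).
#' @param MU Monitor units (default 100).
#' @param step_mm Leaf-position discretization (default 0.1).
#' @return The integral reading in cGy.
#' @export
simulate_sweep_reading <- function(gap_mm, model = leafend_model(),
                                   sweep_range_mm = 120, MU = 100,
                                   step_mm = 0.1) {
  if (gap_mm >= sweep_range_mm)
    stop("gap_mm must be smaller than the sweep range")
  x <- seq(-sweep_range_mm / 2, sweep_range_mm / 2, by = step_mm)
  refine <- max(1L, ceiling(step_mm / 0.02))
  p <- .relative_dose(x, gap_mm, model, refine = refine)
  integral <- sum((p[-1L] + p[-length(p)]) / 2) * step_mm
  MU * model$open_dose_cGy_per_MU * integral / sweep_range_mm
}

#' Simulate closed-bank transmission readings
#'
#' @param model A [leafend_model()].
#' @param MU Monitor units (default 100).
#' @param bank_asymmetry Relative bank difference; banks read
#'   `T * open * (1 -/+ bank_asymmetry/2)`, so their mean stays `T * open`.
#' @return A list with `reading_bank_a`, `reading_bank_b`, `reading_open`.
#' @export
simulate_transmission_reading <- function(model = leafend_model(), MU = 100,
                                          bank_asymmetry = 0) {
  open <- MU * model$open_dose_cGy_per_MU * (1 + model$scatter_fraction)
  Tt <- leaf_transmission(model)
  list(reading_bank_a = Tt * open * (1 - bank_asymmetry / 2),
       reading_bank_b = Tt * open * (1 + bank_asymmetry / 2),
       reading_open = open)
}

#' The simulator's ground-truth sensitometric curve
#'
#' A fixed monotone third-order netOD-to-dose polynomial used to turn
#' simulated dose into film pixel values; its shape is typical of EBT3-class
#' film read in the red channel (netOD about 0.55 at 600 cGy).
#'
#' @return A `calibration_curve` with `r_squared = 1`.
#' @export
truth_calibration <- function() {
  structure(
    list(coefficients = c(0, 100, 1500, 500),
         netod_domain = c(0, 0.60),
         r_squared = 1,
         dose_levels_cGy = seq(0, 600, by = 50),
         monotone = TRUE),
    class = "calibration_curve"
  )
}

#' Render a dose profile as a synthetic film scan
#'
#' Dose is mapped to netOD by inverting the calibration curve (bisection),
#' then to pixel values `PV = pv_unexposed * 10^(-netOD)`, replicated across
#' rows, optionally degraded with Gaussian pixel noise, rounded to integers
#' and clamped to 0..65535. All three channels carry the same signal.
#'
#' @param profile A [dose_profile()] (non-negative doses).
#' @param curve A monotone `calibration_curve` covering the dose range.
#' @param pv_unexposed Unexposed-film pixel value (default 42000).
#' @param noise_sigma_pv Gaussian pixel-noise standard deviation (default 0).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   state. The same seed gives a bit-identical scan.
#' @param n_rows Number of image rows (default 51).
#' @return A `film_scan` whose dpi matches the profile sampling.
#' @export
simulate_film_scan <- function(profile, curve, pv_unexposed = 42000,
                               noise_sigma_pv = 0, seed = NULL,
                               n_rows = 51L) {
  stopifnot(inherits(profile, "dose_profile"),
            inherits(curve, "calibration_curve"))
  h <- profile$positions_mm[2L] - profile$positions_mm[1L]
  netod <- invert_calibration(curve, pmax(profile$dose_cGy, 0))
  pv_row <- pv_unexposed * 10^(-netod)
  pv <- matrix(pv_row, nrow = n_rows, ncol = length(pv_row), byrow = TRUE)
  pixels <- array(pv, dim = c(n_rows, length(pv_row), 3L))
  if (noise_sigma_pv > 0) {
    if (!is.null(seed)) set.seed(seed)
    pixels <- pixels + stats::rnorm(length(pixels), sd = noise_sigma_pv)
  }
  pixels <- pmin(pmax(round(pixels), 0), 65535)
  storage.mode(pixels) <- "integer"
  film_scan(pixels, dpi = 25.4 / h)
}

#' Generate a complete simulated measurement dataset
#'
#' Produces everything the chamber and film pipelines consume for one beam
#' condition: per-gap sweep readings, closed-bank transmission readings,
#' per-gap slit-field film scans at 600 MU, a 13-level calibration set
#' (0-600 cGy in 50 cGy steps) and the model's ground-truth dosimetric gap.
#' All randomness derives from the single `seed`; the same seed reproduces
#' the dataset bit-identically.
#'
#' @param model A [leafend_model()].
#' @param gaps Nominal gap widths in mm (default `c(2,4,6,10,14,16,20)`).
#' @param mu_film Monitor units per slit film (default 600).
#' @param mu_sweep Monitor units per sweep (default 100).
#' @param condition_label,depth_mm Condition bookkeeping.
#' @param calibration_doses Calibration dose levels in cGy.
#' @param pv_unexposed Unexposed-film pixel value.
#' @param noise_sigma_pv Film pixel-noise standard deviation (default 50;
#'   use 0 for noise-free films).
#' @param extent_mm,sampling_mm Film profile geometry; defaults match a
#'   72 dpi scan spanning +/-115 mm.
#' @param seed Integer seed.
#' @return An object of class `simulated_dataset`: `chamber_series` (a
#'   [gap_series()]), `transmission` (a `transmission_result`), `film_scans`
#'   (one `film_scan` per gap, named by gap), `calibration` (data frame with
#'   `dose_cGy`, `pv_exposed`, `pv_unexposed`), `calibration_truth`,
#'   `dlg_true_mm`, `gaps`, `pv_unexposed`, `model`, `seed`.
#' @export
make_dataset <- function(model = leafend_model(),
                         gaps = c(2, 4, 6, 10, 14, 16, 20),
                         mu_film = 600, mu_sweep = 100,
                         condition_label = "6MV", depth_mm = 50,
                         calibration_doses = seq(0, 600, by = 50),
                         pv_unexposed = 42000,
                         noise_sigma_pv = 50,
                         extent_mm = 115, sampling_mm = 25.4 / 72,
                         seed = 1L) {
  set.seed(seed)
  film_seeds <- sample.int(.Machine$integer.max - 1L, length(gaps) + 1L)
  curve <- truth_calibration()
  dlg_true <- reference_dlg(model)

  readings <- vapply(gaps, simulate_sweep_reading, 0, model = model,
                     MU = mu_sweep)
  series <- gap_series(condition_label, depth_mm, gaps, readings)
  tr <- simulate_transmission_reading(model, MU = mu_sweep)
  transmission <- compute_transmission(tr$reading_bank_a, tr$reading_bank_b,
                                       tr$reading_open)

  scans <- lapply(seq_along(gaps), function(i) {
    prof <- simulate_dose_profile(gaps[i], MU = mu_film, model = model,
                                  sampling_mm = sampling_mm,
                                  extent_mm = extent_mm)
    simulate_film_scan(prof, curve, pv_unexposed = pv_unexposed,
                       noise_sigma_pv = noise_sigma_pv,
                       seed = film_seeds[i])
  })
  names(scans) <- paste0("gap_", gaps)

  netod_true <- invert_calibration(curve, calibration_doses)
  pv_exposed <- pv_unexposed * 10^(-netod_true)
  if (noise_sigma_pv > 0) {
    set.seed(film_seeds[length(film_seeds)])
    pv_exposed <- pv_exposed + stats::rnorm(length(pv_exposed),
                                            sd = noise_sigma_pv)
  }
  calibration <- data.frame(dose_cGy = calibration_doses,
                            pv_exposed = round(pv_exposed),
                            pv_unexposed = pv_unexposed)

  structure(
    list(chamber_series = series, transmission = transmission,
         film_scans = scans, calibration = calibration,
         calibration_truth = curve, dlg_true_mm = dlg_true,
         gaps = gaps, pv_unexposed = pv_unexposed, model = model,
         seed = seed),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %s: %d gaps, dlg_true %.4f mm, transmission %.4f, seed %d\n",
    x$chamber_series$condition_label, length(x$gaps), x$dlg_true_mm,
    x$transmission$transmission_fraction, x$seed))
  invisible(x)
}
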