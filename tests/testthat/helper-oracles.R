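# Independent least-squares oracle (normal equations, no lm) and builders
# for the idealized uniform-transmission sweep model
#   Rg = R_open * ((1 - T) * (g + delta) + sweep * T) / sweep
# whose nominal-method DLG is (1 - T) * delta in closed form.

ls_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       x_intercept = -intercept / slope)
}

paper_gaps <- c(2, 4, 6, 10, 14, 16, 20)

idealized_readings <- function(gaps, T, delta, r_open = 1, sweep = 120) {
  r_open * ((1 - T) * (gaps + delta) + sweep * T) / sweep
}

idealized_condition <- function(T, delta, gaps = paper_gaps, r_open = 1,
                                sweep = 120, label = "ideal", depth = 50) {
  list(
    series = gap_series(label, depth, gaps,
                        idealized_readings(gaps, T, delta, r_open, sweep),
                        sweep_range_mm = sweep),
    transmission = compute_transmission(T * r_open, T * r_open, r_open)
  )
}

# Noise-free slit profiles for the frozen default model, computed once per
# test run (shared by several width/integral tests).
.sim_cache <- new.env(parent = emptyenv())
default_profiles <- function() {
  if (is.null(.sim_cache$profiles)) {
    .sim_cache$profiles <- lapply(paper_gaps, simulate_dose_profile,
                                  MU = 600, model = leafend_model())
    names(.sim_cache$profiles) <- paper_gaps
  }
  .sim_cache$profiles
}

# Exact-cubic calibration samples at the standard 13 dose levels.
calibration_truth_samples <- function(doses = seq(0, 600, by = 50)) {
  curve <- truth_calibration()
  data.frame(netod = invert_calibration(curve, doses), dose_cGy = doses)
}
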