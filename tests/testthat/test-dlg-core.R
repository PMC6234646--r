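test_that("transmission fraction is the bank mean over the open reading", {
  expect_equal(compute_transmission(0, 0, 100)$transmission_fraction, 0)
  expect_equal(compute_transmission(1.7, 1.8, 100)$transmission_fraction,
               0.0175)
  # typical measured 6 MV magnitude
  tr <- compute_transmission(1.74, 1.74, 100)
  expect_equal(tr$transmission_fraction, 0.0174)
  expect_equal(tr$reading_open, 100)

  expect_error(compute_transmission(1, 1, 0), "invalid reference")
  expect_error(compute_transmission(1, 1, -5), "invalid reference")
  expect_error(compute_transmission(100, 1, 100), "implausible")
  expect_error(compute_transmission(1, 120, 100), "implausible")
})

test_that("transmission correction is linear, decreasing, and complementary", {
  expect_equal(transmission_correction(0.02, 0, 120), 0.02)
  expect_equal(transmission_correction(0.02, 120, 120), 0)
  expect_equal(transmission_correction(0.0174, 30, 120), 0.01305)
  expect_error(transmission_correction(0.02, 130, 120), "out of range")
  expect_error(transmission_correction(0.02, -1, 120), "non-negative")

  # correction(g) + correction(sweep - g) = R_T for any gap
  set.seed(11)
  g <- runif(50, 0, 120)
  expect_equal(transmission_correction(0.0174, g, 120) +
                 transmission_correction(0.0174, 120 - g, 120),
               rep(0.0174, 50))
})

test_that("corrected readings subtract the correction and flag non-positive results", {
  expect_equal(corrected_reading(0.05, 0), 0.05)
  expect_equal(corrected_reading(0.05, 0.013), 0.037)
  expect_warning(out <- corrected_reading(0.01, 0.013), "non-positive")
  expect_equal(out, -0.003)
})

test_that("fit_dlg matches a normal-equations oracle and rejects degenerate input", {
  # exact line through (2,3),(4,5),(6,7): y = g + 1, x-intercept -1
  est <- fit_dlg(c(2, 4, 6), c(3, 5, 7))
  expect_equal(est$slope, 1)
  expect_equal(est$intercept, 1)
  expect_equal(est$dlg_mm, 1)
  expect_equal(est$r_squared, 1)
  expect_equal(est$n_points, 3L)

  # exact by construction on the standard gap set
  y <- 0.05 * (paper_gaps + 1.4)
  expect_equal(fit_dlg(paper_gaps, y)$dlg_mm, 1.4)

  # noisy points agree with the oracle to machine precision
  set.seed(42)
  yn <- y + rnorm(length(y), sd = 1e-4)
  est <- fit_dlg(paper_gaps, yn)
  oracle <- ls_oracle(paper_gaps, yn)
  expect_equal(est$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(est$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(est$dlg_mm, abs(oracle$x_intercept), tolerance = 1e-12)
  expect_equal(est$r_squared, oracle$r_squared, tolerance = 1e-12)
  expect_lt(abs(est$dlg_mm - 1.4), 0.05)

  expect_error(fit_dlg(c(2, 4), c(1, 2)), "insufficient data")
  expect_error(fit_dlg(c(2, 2, 4), c(1, 1, 2)), "distinct")
  expect_error(fit_dlg(c(2, 4, 6), c(7, 5, 3)), "degenerate fit")
})

test_that("nominal derivation reproduces the closed form of the idealized model", {
  # T = 0: the correction vanishes and the intercept is exactly -delta
  cond <- idealized_condition(T = 0, delta = 1.5)
  expect_equal(derive_dlg_nominal(cond$series, cond$transmission)$dlg_mm, 1.5)

  # T > 0: corrected readings are R_open*(g + (1-T)*delta)/sweep
  cond <- idealized_condition(T = 0.02, delta = 1.5)
  est <- derive_dlg_nominal(cond$series, cond$transmission)
  expect_equal(est$dlg_mm, 0.98 * 1.5)
  expect_equal(est$method_tag, "nominal")

  # no dosimetric extension, any transmission: DLG 0
  cond <- idealized_condition(T = 0.02, delta = 0)
  expect_equal(derive_dlg_nominal(cond$series, cond$transmission)$dlg_mm, 0,
               tolerance = 1e-12)
})

test_that("gap width table validates, looks up exactly, and refuses unlisted gaps", {
  tab <- default_gap_width_table()
  expect_equal(lookup_gap_width(tab, 2), 30)
  expect_equal(lookup_gap_width(tab, 20), 90)
  expect_equal(lookup_gap_width(tab, c(4, 16)), c(40, 80))
  expect_error(lookup_gap_width(tab, 3), "not in the table")
  expect_equal(lookup_gap_width(tab, 3, interpolate = TRUE), 35)

  expect_error(gap_width_table(c(2, 4), c(30, 25)), "increasing")
  expect_error(gap_width_table(c(2, 4), c(1, 5)), "cannot be smaller")
})

test_that("cross-field derivation reduces to nominal for an identity table and exceeds it otherwise", {
  cond <- idealized_condition(T = 0.02, delta = 1.5)
  identity_tab <- gap_width_table(paper_gaps, paper_gaps)
  nom <- derive_dlg_nominal(cond$series, cond$transmission)
  cf_id <- derive_dlg_crossfield(cond$series, cond$transmission, identity_tab)
  for (field in c("slope", "intercept", "dlg_mm", "r_squared", "n_points"))
    expect_identical(cf_id[[field]], nom[[field]])

  # the measured table adds T*(g_D - g_N)/sweep > 0 to every corrected
  # reading's subtraction... i.e. raises the line, pushing the intercept out
  cf <- derive_dlg_crossfield(cond$series, cond$transmission)
  expect_gt(cf$dlg_mm, nom$dlg_mm)
  expect_equal(cf$method_tag, "crossfield")

  # with T = 0 the table is inert
  cond0 <- idealized_condition(T = 0, delta = 1.5)
  nom0 <- derive_dlg_nominal(cond0$series, cond0$transmission)
  cf0 <- derive_dlg_crossfield(cond0$series, cond0$transmission)
  expect_equal(cf0$dlg_mm, nom0$dlg_mm)

  # a series gap missing from the table names the gap
  short_tab <- gap_width_table(c(2, 4, 6, 10, 14, 16), c(30, 40, 50, 60, 70, 80))
  expect_error(derive_dlg_crossfield(cond$series, cond$transmission, short_tab),
               "20")
})

test_that("series validation enforces the measurement invariants", {
  expect_error(gap_series("x", 50, c(2, 4), c(1, 2)), "at least 3")
  expect_error(gap_series("x", 50, c(2, 4, 4), c(1, 2, 3)), "increasing")
  expect_error(gap_series("x", 50, c(-2, 4, 6), c(1, 2, 3)), "positive")
  expect_error(gap_series("x", 50, c(2, 4, 130), c(1, 2, 3)), "sweep range")
  expect_error(gap_series("x", 50, c(2, 4, 6), c(1, -2, 3)), "positive")
})

test_that("batch derivation matches single-condition calls and survives failures", {
  c1 <- idealized_condition(T = 0.02, delta = 1.5, label = "6MV", depth = 50)
  c2 <- idealized_condition(T = 0.02, delta = 1.5, label = "6MV", depth = 100)
  c3 <- idealized_condition(T = 0.035, delta = 2.0, label = "10MV", depth = 50)

  out <- batch_derive(list(c1, c2, c3))
  expect_equal(nrow(out), 6L)
  expect_equal(sort(unique(out$method)), c("crossfield", "nominal"))

  # the model is depth-free: both depths give identical DLGs per method
  d1 <- out[out$condition == "6MV" & out$method == "nominal", ]
  expect_equal(d1$dlg_mm[1], d1$dlg_mm[2], tolerance = 1e-9)

  # per-condition rows equal the single-condition results exactly
  single <- derive_dlg_crossfield(c3$series, c3$transmission)
  got <- out[out$condition == "10MV" & out$method == "crossfield", ]
  expect_identical(got$dlg_mm, single$dlg_mm)
  expect_identical(got$slope, single$slope)

  # a broken condition is reported without stopping the batch
  bad <- c1
  bad$series$entries$reading <- rev(sort(bad$series$entries$reading))
  out2 <- batch_derive(list(bad, c3))
  expect_true(any(!is.na(out2$error)))
  expect_true(any(is.na(out2$error)))
  expect_error(batch_derive(list()), "non-empty")
})
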