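---
title: "Determining the dosimetric leaf gap from sweeping-gap and film measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the dosimetric leaf gap from sweeping-gap and film measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlgcal)
```

## The problem

Most multileaf collimators (MLCs) have rounded leaf ends moving on straight
trajectories. X rays leak through the curved tip, so the dosimetric width of
a leaf-pair gap exceeds its geometric width. Treatment planning systems
model this with a single per-energy parameter, the dosimetric leaf gap
(DLG): an effective widening applied to every opposing leaf pair. An
inaccurate DLG propagates into every dynamic-MLC (IMRT/VMAT) dose
calculation, so its determination is a core commissioning task.

The standard measurement sweeps a fixed leaf gap of width $g$ at constant
speed across an ionization chamber and records the integral reading $R_g$
for a series of gaps. During the sweep the chamber is shielded by the leaves
whenever the gap is elsewhere, so each reading contains a transmission
contribution that must be removed before extrapolation:

$$R_{gT} = R_T \left[1 - \frac{g}{120\,\mathrm{mm}}\right], \qquad
  R_g' = R_g - R_{gT},$$

where $R_T$ is the mean closed-bank transmission and 120 mm is the total
sweep travel. A straight line fitted to $R_g'$ versus the nominal gap
crosses zero at a negative gap; the absolute value of that gap-axis
intercept is the DLG.

The subtlety this package exists for is the choice of $g$ inside $R_{gT}$.
The conventional (vendor) prescription uses the nominal gap. But the leaves
shield the chamber only outside the *dose* extent of the slit — which is far
wider than the nominal gap because of penumbra, phantom scatter and tip
transmission. Static slit films show a 2 mm gap producing measurable dose
over about 30 mm, and a 20 mm gap over about 90 mm. Substituting this
cross-field dose width $g_D$ for the nominal width $g_N$ in $R_{gT}$ (and
only there — the regression abscissa stays nominal, because the DLG must
remain a leaf-position offset in nominal coordinates) raises each corrected
reading by $R_T (g_D - g_N)/120$ and pushes the intercept outward. On the
idealized uniform-transmission model the nominal method returns
$(1-T)\Delta$ for a true extension $\Delta$, while the cross-field method
returns a larger value; the difference is typically several tenths of a
millimetre — the size of leaf-position error that is clinically relevant.

## What the package computes

* `derive_dlg_nominal()` / `derive_dlg_crossfield()` implement the two
  correction conventions over a `gap_series` (readings vs gap) and a
  `transmission_result` ($R_T$ from bank A, bank B and open readings).
  Readings are unit-agnostic; internally they are normalized to the open
  reading so the correction and the readings share one scale. The DLG is
  invariant under that common scaling.
* `default_gap_width_table()` carries the measured $g_N \to g_D$ mapping
  (30–90 mm for gaps 2–20 mm), which was found to be essentially
  energy-independent. Lookups of unlisted gaps fail loudly; interpolation is
  opt-in.
* The film chain (`read_scan()`, `net_od()`, `fit_calibration()`,
  `to_dose()`, `extract_profile()`, `match_background_tail()`,
  `cross_field_width()`, `integral_dose()`, `derive_dlg_film()`) measures
  $g_D$ and provides an independent DLG estimate from the integral dose of
  static slit films, regressed against the nominal gap with the same
  intercept rule.
* `leafend_model()` and `make_dataset()` generate synthetic measurements
  with a known ground truth, so every estimator can be tested end to end
  without a linac.

## Worked example

```{r example}
ds <- make_dataset(seed = 1)                  # full synthetic measurement set
nom <- derive_dlg_nominal(ds$chamber_series, ds$transmission)
cf  <- derive_dlg_crossfield(ds$chamber_series, ds$transmission)
c(truth = ds$dlg_true_mm, nominal = nom$dlg_mm, crossfield = cf$dlg_mm)
```

The nominal method lands close to $(1-T)$ times the true dosimetric
extension; the cross-field method is deliberately larger — on real
measurements it is the one that agrees with film and with plan-optimized
values.

## The film chain and its conventions

Scans are 48-bit RGB TIFFs at 72 dpi, read verbatim (the protocol disables
all scanner processing; the reader refuses non-16-bit files rather than
rescale silently). Only the red channel is used. Net optical density is
computed as $\mathrm{netOD} = \log_{10}(PV_\mathrm{unexposed}/PV_\mathrm{exposed})$,
which equals the OD difference for any common reference, so no
scanner-maximum constant enters. Dose is a third-order polynomial in netOD,
fitted over 13 levels from 0 to 600 cGy; the fit's $R^2$ is the routine
stability check (values below ~0.999 indicate a handling or scanning
problem).

Profiles are column means over a band of rows about the slit's long axis,
converted to mm at 25.4/72 mm per pixel. Films carry no coordinate
registration, so the origin is the dose-weighted centroid of the
above-half-maximum core, which is insensitive to the background level. The
width of the region at or above a fraction $f$ of the net peak is reported
as the distance between the outermost qualifying samples.

Three conventions here are this package's explicit choices, because the
measurement protocol leaves them open:

* **Background matching.** Each film's background (transmission plus
  response offset) is the mean dose in two symmetric windows far from the
  slit, by default 85–105 mm from center; all profiles are shifted so the
  tails sit at a common level (default 0). The window default sits at least
  two scatter decay lengths beyond the widest measured field (half-extent
  45 mm), where residual slit dose is below 0.1% of peak; windows closer in
  would bias the widths of the large gaps.
* **Width rule.** The cross-field width uses a threshold of $f = 0.005$ of
  the net peak, optionally rounded to a 10 mm grid. The dose widths one
  actually tabulates are round numbers, and with the default simulator this
  rule reproduces the 30–90 mm mapping exactly; both $f$ and the grid are
  arguments, not constants.
* **No transmission term in the film regression.** The film DLG relies on
  tail matching alone to remove the transmission background from each
  integral; no sweeping-gap-style $R_{gT}$ subtraction is applied. This is
  an interpretation — the integral of a background-matched profile is
  already the net slit contribution.

## The synthetic-data generator

`leafend_model()` is a parametric stand-in for the linac and scanner, built
to exercise the estimators, not to reproduce any particular MLC's tip
physics. A ray at depth $d$ behind a tip of radius $R$ traverses the chord
$\min(t, 2\sqrt{R^2 - (R-d)^2})$ of leaf material ($t$ = full thickness) and
is attenuated as $e^{-\mu \cdot \mathrm{path}}$; a slit's fluence is the
product of the two banks' attenuations with tips at $\mp g/2$. The dose
profile is the fluence convolved with a unit-integral Gaussian source
kernel, plus `scatter_fraction` times the fluence convolved with a broad
unit-integral exponential kernel. The scatter kernel is exponential rather
than Gaussian by necessity: the measured dose widths grow nearly linearly
with the gap (30 mm at $g$ = 2 up to 90 mm at $g$ = 20), and a Gaussian
tail's reach at a fixed threshold grows only like the square root of the
log of the slit amplitude — no single-Gaussian parameterization reaches the
gap-20 width without overshooting the gap-2 one. An exponential tail's
reach is linear in that log, which matches the table's shape.

Defaults (tip radius 80 mm, thickness 60 mm, $\mu$ fixed by a closed-leaf
transmission of 1.74%, source $\sigma$ 1.5 mm, scatter fraction 0.095 with
18.5 mm decay length, 0.9 cGy/MU output) were calibrated once against the
full width-measurement pipeline — tail-window background matching included —
so that the $f = 0.005$ + 10 mm rule lands on the 30–90 mm table with at
least 1 mm of rounding margin for every gap, and then frozen. The ground
truth `reference_dlg()` is the integral of the net unconvolved fluence of a
probe slit minus the probe width; it is independent of the probe gap once
the tip shadows separate (stable to well under 0.02 mm over 6–20 mm probes)
and independent of the blurring kernels, which integrate to one.

What the generator emulates: transmission backgrounds, broad scatter tails,
penumbra, film noise in pixel-value space, integer quantization, and the
unit structure of chamber readings. What it does not: divergent-beam ray
tracing through the true tip shape, inter-leaf leakage and tongue-and-groove
structure, scanner lateral-response artifacts, film-darkening kinetics, and
depth dependence (depth is a label; the real measurement is depth-insensitive
to within 0.07 mm, and the simulator mirrors that by construction). Passing
the recovery tests therefore demonstrates that the estimators are correct
for the model class — transmission plus blurred slit plus additive tails —
not that the simulator predicts any specific linac.

## Numerical choices

* Sweep readings integrate the profile over leaf positions with 0.1 mm
  steps and trapezoidal accumulation. The fluence has a slope discontinuity
  at each tip edge, so convolutions run on an internally refined grid
  (0.02 mm for sweeps, 0.05 mm for film profiles) and are decimated back;
  at coarse sampling alone the discrete convolution acquires a small
  additive bias in every reading, which an intercept method inherits
  one-for-one (about 0.02 mm here).
* Convolutions use FFTs zero-padded to a highly composite length;
  edge-value padding is exact because the far field is a constant
  transmission plateau.
* Calibration inversion (dose to netOD, used only when synthesizing films)
  is bisection on the monotone branch to $10^{-6}$ netOD.
* Non-positive corrected readings are kept in the fit and flagged with a
  warning — silently dropping points would change the regression. A zero or
  negative fitted slope is an error naming the slope.
* Degenerate inputs fail loudly: fewer than three gaps, duplicate gaps,
  bank readings at or above the open reading, gap widths beyond the sweep
  range, tail windows overlapping the slit, non-invertible dose requests.

## Problem sizes and test design

The test suite and the acceptance script run entirely on generated data:
seven gaps per condition, 652-sample profiles (±115 mm at 72 dpi), 51-row
scans, 13 calibration levels, and 10–100 replicate loops where a stability
band is asserted. These sizes keep a full run in the tens of seconds while
leaving every estimate's error an order of magnitude inside its asserted
tolerance. Chamber-side oracles are closed forms of the idealized
uniform-transmission model ($R_g = R_\mathrm{open}[(1-T)(g+\Delta) +
120T]/120$, nominal DLG $= (1-T)\Delta$) and an independent
normal-equations least-squares implementation; film-side oracles are
round-trips through the known calibration curve and the simulator's
`reference_dlg()`.

## Known limitations

* The simulator's tip model is a declared surrogate; no claim depends on
  its physical fidelity beyond the frozen width mapping.
* The film chain implements a single-channel (red) workflow with a fixed
  central ROI convention; multichannel dosimetry and scanner-uniformity
  maps are out of scope.
* The cross-field table refuses unlisted gaps by design; measuring a new
  gap set requires films for those gaps (or explicit interpolation).
* Plan-based DLG optimization (TPS dose calculation, gamma analysis) is
  outside the package: the cross-field DLG is the *starting* value such a
  process would refine.
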