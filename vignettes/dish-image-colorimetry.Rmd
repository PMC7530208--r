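---
title: "Quantifying activated-sludge biomass from dish images: models, parameters and design notes"
author: "sludgeRGB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activated-sludge biomass from dish images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sludgeRGB)
```

## The measurement model

An activated-sludge sample poured into a shallow transparent dish and
photographed under fixed lighting darkens with growing biomass
concentration (MLSS, g/L): suspended flocs absorb and scatter the
transmitted light. `sludgeRGB` treats the mean 8-bit channel intensities of
the dish interior as the measurement, and models them in two regimes:

* **Linear calibration** over the full working range (0–15 g/L):
  $V_c = a_c + M_c \cdot \mathrm{MLSS}$ per channel $c \in \{R, G, B\}$,
  fitted by ordinary least squares with intensity as the response. The
  regression runs in this direction because the grayscale weights are
  defined from the intensity-per-g/L slopes; MLSS is recovered afterwards
  by inverting the line, not by re-regressing MLSS on intensity.

* **Beer–Lambert (optical diffuse) regime** at low turbidity:
  $V_c = V_{0,c}\,e^{-\kappa_c \cdot \mathrm{MLSS}}$. When absorption still
  dominates over multiple scattering, transmitted intensity decays
  exponentially in the absorber concentration. As turbidity grows,
  scattering breaks the assumption, which is why the model carries an
  explicit validity bound `mlssMax`.

The slope-weighted grayscale composite
$\mathrm{Gray} = K_R R + K_G G + K_B B$ with
$K_c = M_c / (M_R + M_G + M_B)$ compresses the three channels into one
index. Because the weights are normalized slopes they sum to one, so a
neutral pixel maps to itself, and the composite's own calibration slope is
the mean-square-optimal blend of the three channel sensitivities under this
normalization. The weights are computed from *signed* slopes with a
same-sign precondition: on darkening cultures all three slopes are
negative and the weights land in (0, 1), while mixed signs (a channel
brightening as others darken) indicate pathological data and fail loudly
rather than produce weights outside (0, 1).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `shrink` (`meanRGB`) | 0.8 | — | Radius multiplier excluding the dish rim and meniscus highlights from the average. The protocol this package formalizes cropped dishes by hand and states no rule; 0.8 keeps a comfortable margin inside a rimmed 54 mm dish. |
| `threshold` (`detectDishROI`) | 20 | intensity | Minimum per-channel deviation from the border-estimated background for a pixel to count as dish. Well below the rim/background contrast of any usable photograph, well above sensor noise. |
| `mlssMax` (`fitExponential`) | 8 | g/L | Upper bound of the diffuse regime; beyond it multiple scattering makes the log-linear model visibly lack of fit for activated sludge. |
| saturation warning | 0.01 | fraction | Fraction of in-ROI pixels clipped at 255 above which extraction warns; clipped pixels bias channel means downward in truth. |
| `clip` (prediction) | `FALSE` | — | Estimates are flagged (`below-zero`, `above-calibration-range`), never silently clipped; clipping to zero is opt-in for operational dashboards. |

MAPE excludes samples with actual MLSS = 0 (the relative error is undefined
there); the number of excluded points is reported alongside the statistic so
the rule is visible in the output.

## The bundled reference calibration

`referenceCalibration()` ships 23 dish measurements spanning MLSS 0 to
14.901 g/L, each the average of three images. Two rows (MLSS 12.98 and
13.52 g/L) are marked `in_reference_fit = FALSE`: the canonical reference
slopes $(M_R, M_G, M_B) = (-5.3117, -8.9099, -14.404)$, the grayscale
weights $(0.186, 0.311, 0.503)$ and the error statistics this dataset
reproduces all derive from the remaining 21 samples, and refitting on all
23 rows shifts the red slope by about 5%. The two extra rows are retained
for validation; `referenceCalibration(fittedOnly = TRUE)` returns the
21-row fitting subset. A related historical quirk worth knowing: legacy
reports of this calibration quote a "RMSE" column that is actually
$\sqrt{\sum e_i^2}$ without the $1/n$, and a gray-row value inconsistent
with any standard definition (it falls below the MAE). `sludgeRGB` reports
only the standard definitions, under which RMSE ≥ MAE always holds.

On the reference fit the channel R² ordering is B (0.990) > G (0.970) >
R (0.900), with the gray composite at 0.9925 — slightly above blue, which
is why `selectBestChannel()` takes a `channels` argument: among the three
primaries blue wins, while the composite edges it out once included.

## What the synthetic generator emulates

`sceneConfig()` describes a dish scene: geometry (centre, radius, rim
width), colours (background, rim, interior at MLSS 0), per-channel
attenuation coefficients, and additive Gaussian sensor noise applied before
8-bit quantization, with clamping at 0/255 modelling sensor saturation. The
defaults are chosen to mimic the reference calibration: base colour
(232, 232, 234) matches its zero-MLSS sample, and attenuation
(0.020, 0.038, 0.090) per g/L matches the low-MLSS exponential fits of its
three channels, preserving the physically expected ordering
$\kappa_B > \kappa_G > \kappa_R$. The default noise of 1 intensity unit is
typical shot/readout noise for a well-exposed consumer sensor at base ISO.

Seeding is hierarchical: one root seed in the config, with each image's
stream derived from the (sample, replicate) indices, so any single image
regenerates identically in isolation and the caller's RNG state is never
disturbed.

`generateSeries()` has two paths. The default analytic shortcut emits each
replicate's channel means directly as the attenuated value plus Gaussian
noise of sd $\sigma/\sqrt{n_\mathrm{pixels}}$ — the exact sampling
distribution of a mean over that many independent pixels, minus
quantization — and keeps property tests over hundreds of simulated series
cheap. The rasterized path (`rasterize = TRUE`, always used when images are
written) renders full images and runs them through the real extraction
code. Tests use the rasterized path wherever the imaging code itself is
under test: a 9-point MLSS grid on 200×200 px scenes recovers each
configured attenuation coefficient within 5% at noise sd 2.

What the generator does **not** emulate: meniscus optics, vignetting,
specular highlights, floc texture, illumination drift and white-balance
error. Passing tests therefore demonstrate correctness of the computational
pipeline under the stated optical model, not robustness of the photography
protocol itself — the latter still requires disciplined capture conditions
(fixed lighting, exposure and geometry).

## Numerical choices and degenerate inputs

* A pixel belongs to a circular ROI iff its centre satisfies
  $(x-c_x)^2 + (y-c_y)^2 < r^2$ (strict, no antialiased partial weighting):
  deterministic and exactly testable. Pixel centres sit at half-integer
  coordinates with the origin at the top-left corner.
* Channel means are computed on raw stored 8-bit values — no gamma
  linearization or colour-space transform — because the calibration is
  defined directly on stored values and any monotone transform would be
  absorbed into it.
* Replicate averaging is unweighted regardless of per-image pixel counts,
  matching the three-plain-images protocol.
* The exponential model is fitted by log-linear least squares:
  deterministic, closed-form, no starting values. Both the log-scale and
  intensity-scale R² are reported because fit quality for such models is
  quoted inconsistently across the literature; on the reference blue
  channel they are 0.981 and 0.976.
* Dish detection thresholds against the border-median background, labels
  connected components, and accepts the largest only if its bounding box is
  square within 20% and its fill factor is disk-like; anything else, or a
  circle cut by the image border, is an explicit error suggesting an
  explicit ROI. Explicit ROIs always take precedence in pipelines.
* Degenerate designs fail with dedicated condition classes: fewer than 3
  usable samples (input error), all-identical MLSS, zero or mixed-sign
  slopes, non-positive intensities under the log, zero-slope inversion
  (degeneracy errors). The CLI maps these to distinct exit codes (3 and 4)
  with option mistakes at 2.
* Model JSON is written with 17 significant digits so every stored double
  round-trips bit for bit.

## Problem sizes in the test suite

The suite fits on modest hardware by construction: property tests use the
analytic generator (hundreds of series in milliseconds), and rasterized
end-to-end tests use one 400×400 px scene for ROI detection plus 200×200 px
scenes for the 9-point attenuation-recovery grid. The full suite runs in a
few seconds; `scripts/acceptance.R` in well under a minute.

## Known limitations

* Calibrations are camera-, lighting- and dish-specific; there is no
  calibration-transfer mechanism between setups.
* No uncertainty intervals accompany predictions; the error statistics are
  in-sample summaries of the calibration, not predictive intervals.
* The linear/exponential model choice is left to the user; the package
  flags out-of-range predictions but does not switch models automatically.
* Extremely dark (near-zero blue) or saturated images violate the model
  assumptions; the saturation QC flags the latter, while the former shows
  up as out-of-range flags on inversion.
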