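---
title: "Hyperspectral retinal oximetry: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral retinal oximetry: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinox)
library(dplyr)
```

## The measurement model

A snapshot hyperspectral fundus camera records the retina over 450–700 nm
in roughly 76 bands (~3.3 nm spacing). Light returning from a pixel over a
retinal vessel has passed through the blood column, so the vessel's
optical density against the neighbouring fundus background,

$$\mathrm{OD}(\lambda) = \log_{10}\frac{I_\mathrm{ref}(\lambda)}{I_\mathrm{vessel}(\lambda)},$$

carries the hemoglobin absorption spectrum. We model it with a modified
Beer–Lambert law that stays linear in its coefficients:

$$\mathrm{OD}(\lambda) \approx a\,\varepsilon_{\mathrm{HbO_2}}(\lambda)
  + b\,\varepsilon_{\mathrm{Hb}}(\lambda) + g(\lambda),$$

with $a = Lcs$ and $b = Lc(1-s)$ for optical path $L$ (cm), total
hemoglobin $c$ (mol/L) and oxygen saturation $s$, and an additive
scatter/offset term $g$. The "modification" of the plain Beer–Lambert law
is exactly this additive term: wavelength-dependent scattering, lens and
media losses, and double-pass geometry do not cancel in the OD ratio, but
to first order they vary smoothly with wavelength. We parameterise $g$ as
a constant plus a linear term in $\lambda$ by default (a constant-only
mode exists). This is the standard linearisation; it keeps the fit an
ordinary least-squares solve and makes the estimator's invariances exact
and testable.

The saturation estimate is the amplitude ratio

$$\hat s = \frac{a}{a+b},$$

which cancels $L$ and $c$: it is invariant to vessel caliber, hematocrit,
overall OD amplitude and — through the constant column — to any additive
OD offset. These invariances are asserted directly in the test suite.
$\hat s$ outside $[0,1]$ is clipped and flagged rather than constrained
during optimisation; we prefer a transparent linear solve whose raw
coefficients remain inspectable (`so2_raw`, `clipped`, `degenerate`) over
a constrained fit that hides pathology. A fit with $a+b \le 0$ has no
meaningful saturation and is flagged degenerate with `so2 = NA`.

## Extinction spectra

The package embeds a compiled table of molar extinction coefficients of
oxy- and deoxyhemoglobin over 450–700 nm (units cm⁻¹·(mol/L)⁻¹ of
hemoglobin tetramer), assembled from standard public compilations of the
visible-band spectra. It reproduces the landmarks that drive oximetry: the
HbO₂ α/β double peak at 542/577 nm, the Hb peak at 555 nm, isosbestic
crossings near 500, 530, 548, 569 and 586 nm, and the large deoxy/oxy
contrast in the red (≈10× at 660 nm). Band values are obtained by
piecewise-linear interpolation — monotone, exact at the knots and bounded
between them, which is sufficient at ~3 nm band spacing and avoids spline
overshoot near the steep 577→590 nm flank. Exact numeric agreement with
any particular instrument calibration is deliberately not claimed; the
same table drives both the forward simulation and the unmixing, so the
pipeline is self-consistent, and all quantitative claims in this package
are about recovery of known ground truth, not about absolute calibration
transfer.

## Choosing the 28 fit wavelengths

The fit uses 28 of the 76 bands. Their identities are a design choice
made here explicitly, deterministic and configurable
(`select_fit_wavelengths()`): from the bands in 500–600 nm — where
hemoglobin dominates the signal and detector response is strong — take
the two bands nearest an isosbestic crossing (smallest
$|\varepsilon_{\mathrm{HbO_2}}-\varepsilon_{\mathrm{Hb}}|$) as amplitude
anchors, then fill with the bands of largest oxy/deoxy contrast; ties
break toward shorter wavelengths. Isosbestic anchors pin the total
hemoglobin amplitude $a+b$ independently of $s$, which conditions the
ratio estimate; the high-contrast bands carry the saturation information.
With fewer in-window candidates than requested the selection widens to
the whole grid, so the rule degrades gracefully on coarse band sets.

```{r}
sel <- select_fit_wavelengths(make_band_grid())
length(sel); range(sel)
```

## The synthetic fundus generator

The generator emulates the study system — the rabbit retina, whose
vasculature is confined to horizontal "medullary ray" streaks — at the
level needed to exercise the estimator:

* **Geometry.** A 100 × 140 px scene at 10 µm/pixel with paired
  artery/vein on the temporal and nasal sides (`rvo_scene()`). Default
  calibers 75 µm (artery) and 125 µm (vein, the caliber the occluding
  laser spot is sized to); anything down to ~50 µm (5 px) renders.
* **Forward model.** Background pixels carry
  `illumination × reflectance(λ)` (default reflectance 0.6 with a mild
  positive spectral slope); vessel pixels are attenuated by
  $10^{-\mathrm{OD}(\lambda)}$ with $L$ = `path_length_scale` × diameter
  (default scale 1: a single transit, with double-pass effects folded
  into the fitted amplitude), $c$ = 2.3 mmol/L (≈150 g/L whole blood) and
  the scene's scatter term. Vessels are rendered as uniform slabs, so
  every vessel pixel shares the exact analytic OD.
* **Scatter modes.** The default scatter term (g0 = 0.08,
  g1 = 2×10⁻⁴ nm⁻¹, linear in λ) lies *inside* the fitting class, so
  noise-free inversion is exact — this is what makes deterministic
  end-to-end recovery targets well-posed. A wavelength power-law mode
  (`mode = "powerlaw"`) lies outside the fit class and exists to stress
  the estimator under model mismatch.
* **Noise.** Per-band independent Gaussian noise, default σ = 1% of the
  illumination level, seeded per scene; Poisson shot noise with gain is
  available. Same seed ⇒ bit-identical cubes.
* **Cohorts.** `cohort_spec()` draws per-animal saturations per arm
  (temporal/nasal × artery/vein) either fixed at the arm mean or
  normal(mean, sd); occlusion is a per-timepoint saturation delta on the
  occluded arms; a recannulation timepoint returns every vessel to the
  animal's own baseline value. Presets carry the study conditions: the
  main paired cohort (n = 20, baseline temporal artery/vein
  85.1 ± 6.1 / 71.4 ± 5.5%, nasal 85.2 ± 7.6 / 69.2 ± 6.2%, one-hour
  deltas −4.5 and −7.4 points on the temporal side), two zero-delta
  laser-control arms (n = 5 each) and a three-animal recannulation time
  course.
* **Pre/post correlation.** Follow-up draws are correlated with baseline
  at ρ = 0.7 by default: a paired design implies positive within-animal
  correlation, and power/type-I simulations need the value declared. It
  is configurable; the study itself reports no correlation estimate, so
  this is a package choice, not a reproduced value.

What the generator does **not** emulate: photon transport (no Monte-Carlo
radiative transfer, no pigmentation or media-opacity classes), vessel
edge partial-volume profiles, hemorrhage or edema, motion between
timepoints, and collateral retrograde filling (the study attributes
animal-to-animal variability to it, but gives no parametric form — we use
independent per-animal draws instead). Passing recovery tests on these
scenes therefore demonstrates correctness of the estimator and pipeline
plumbing, not robustness to every real-fundus confounder.

## Vessel extraction

Detection operates on the single band nearest 570 nm, where hemoglobin
contrast is high: pixels darker than 0.7× the image median are labelled
into connected components (≥ 20 px). Each component gets a principal-axis
centerline, a width estimate (area / axial length), a core pixel set (the
central 50% of the width, avoiding edge partial-volume pixels) and
flanking reference strips offset 2 vessel widths to each side, excluding
a one-pixel-dilated union of all vessel masks. OD uses 10%-trimmed means
of both pixel sets — robust to stray pixels, and exact on noise-free
scenes where core pixels are identical. The sampling rules (offset,
trim, core fraction) are declared package choices; zero vessel means are
capped at OD 6 with a warning, and non-positive reference means are hard
errors naming the band. A ground-truth bypass (`segments_from_truth()`)
builds segments straight from the generator's label image so estimator
tests do not depend on detection.

## Statistics

Arm summaries are mean ± SD per (timepoint, kind, region); pre/post
comparisons use the paired, two-tailed Student t-test
(`stats::t.test(paired = TRUE)` with explicit degenerate handling:
identical pairs give t = 0, p = 1; zero-variance nonzero differences give
a p = 0 sentinel with a warning). Multiple vessel segments of one arm are
averaged per animal before testing, so the analysis unit is the animal;
per-segment reporting is available via a flag. No multiple-testing
correction is applied, matching per-comparison reporting. Saturations are
percent (0–100) at every user-facing surface and fractions internally.

## Numerical and interface choices

* Base-10 logarithm for OD, matching the decadic extinction convention.
* The scatter wavelength column is centred and scaled ((λ − 575)/100) for
  conditioning; the least-squares solve is QR-based with an explicit rank
  check (an all-isosbestic design is a hard "degenerate design" error).
* Coordinates are 1-based (row, col) matrices, R's native convention;
  wavelengths travel with every cube.
* The ENVI-style writer defaults to 64-bit floats so write/read
  round-trips are bit-exact for double-precision cubes; 32-bit storage is
  available where compactness matters. The TIFF-stack dialect stores
  32-bit pages scaled to [0, 1] with the scale in the wavelength sidecar.
* Every output CSV carries provenance (`# retinox <version>`, seed,
  config hash) as comment lines that `readr` skips on read.

## Problem sizes

The test suite and acceptance script are sized for a single CPU: the
end-to-end cohort runs use 20 animals × 2 timepoints at 100 × 140 × 76
(seconds per cohort); noise-robustness uses 200 replicates of a
40 × 60 × 76 single-vessel scene; t-test calibration uses 500 null
cohorts and the control-arm check 300 seeded cohorts at the
measurement level. These sizes give Monte-Carlo error comfortably below
the asserted tolerances (e.g. the type-I fraction over 500 simulations
has a standard error of ~1%, against an asserted window of ±2%).

## Known limitations

Absolute calibration to a physical instrument is out of scope: no in-vivo
calibration transfer, no vessel-diameter or pigmentation correction, and
the embedded extinction compilation is not tied to a specific device.
Detection is deliberately simple (single-band threshold + connected
components) and is not a human-grade fundus segmenter: it assumes
well-separated, roughly straight vessels on a smooth background, which
the generator provides and real fundus images may not. The cohort model
treats animals as exchangeable and does not model the multi-week time
course beyond per-timepoint deltas; repeated-measures modelling is
intentionally absent because the emulated analysis uses paired t-tests
only.
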