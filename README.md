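# retinox

Hyperspectral retinal oximetry: estimating the oxygen saturation (SO₂) of
retinal arteries and veins from snapshot hyperspectral fundus image cubes,
with a synthetic scene generator emulating a rabbit retinal-vein-occlusion
(RVO) study.

## The problem

Retinal vein occlusion is presumed to damage the retina through hypoxia,
but intravascular oxygen content is hard to measure non-invasively. A
hyperspectral fundus camera records the retina at ~76 spectral bands over
450–700 nm in a single flash, so every vessel carries a full absorption
spectrum. Because oxygenated and deoxygenated hemoglobin have distinct
molar extinction spectra — ε_HbO₂(λ) and ε_Hb(λ) cross at the isosbestic
points near 500, 530, 548, 569 and 586 nm and differ tenfold at 660 nm —
the saturation of the blood column can be read off the vessel's optical
density spectrum.

## The model

For a vessel segment, the optical density against the adjacent fundus
background at wavelength λ is

```
OD(λ) = log10( I_ref(λ) / I_vessel(λ) )
```

and is modelled by a modified Beer–Lambert law, linear in its
coefficients:

```
OD(λ) ≈ a · ε_HbO₂(λ) + b · ε_Hb(λ) + g(λ)
```

where `a = L·c·s`, `b = L·c·(1−s)` (path length `L`, total hemoglobin `c`,
saturation `s`) and `g(λ)` is an additive scatter/offset term (constant +
linear in λ by default). The fit is an ordinary least-squares solve over a
deterministic selection of 28 wavelengths in 500–600 nm (the most
oxy/deoxy-discriminating bands plus two near-isosbestic amplitude
anchors), and the saturation estimate is the amplitude ratio

```
ŝ = a / (a + b)
```

which is invariant to overall OD amplitude (vessel caliber, hematocrit,
illumination) and to additive offsets. Saturation maps are pseudocolored
on a linear blue (0%) → red (100%) scale.

Because the original animal imaging data are not deposited, the package
includes a first-class synthetic generator: medullary-ray fundus scenes
with artery/vein pairs on the temporal and nasal sides, rendered through
the same Beer–Lambert forward model with known ground-truth saturations,
plus paired pre/post cohort scenarios (occlusion deltas on the temporal
side, nasal vessels as within-eye controls, laser-control arms,
spontaneous recannulation). Cohort statistics mirror the study design:
per-arm mean ± SD summaries, paired two-tailed Student t-tests, and
arteriovenous differences.

## Worked example

```r
library(retinox)
library(dplyr)

# render a synthetic fundus cube (100 x 140 px, 76 bands, 4 vessels)
cube <- render_cube(rvo_scene(), make_band_grid(), hb_extinction())

# detect vessels, compute OD spectra, unmix
segs <- annotate_segments(detect_vessels(cube), cube)
fits <- fit_so2(compute_od(cube, segs))
glance(fits) |>
  inner_join(segs[, c("segment_id", "kind", "region")], by = "segment_id") |>
  select(segment_id, kind, region, so2_percent, residual_norm)
#> # A tibble: 4 × 5
#>   segment_id kind   region   so2_percent residual_norm
#>        <int> <chr>  <chr>          <dbl>         <dbl>
#> 1          1 vein   temporal        71.4      7.55e-16
#> 2          2 artery temporal        85.1      6.16e-16
#> 3          3 vein   nasal           69.2      7.97e-16
#> 4          4 artery nasal           85.2      9.44e-16
```

The scene's ground-truth saturations (71.4% temporal vein, 85.1% temporal
artery, 69.2%/85.2% nasal) are recovered exactly: the noise-free forward
model lies inside the fitting class, so the residuals are at machine
precision. A stochastic paired cohort reproduces the study's statistics:

```r
spec <- rvo_cohort_preset("rvo-baseline", sampling = "normal", seed = 1)
meas <- cohort_truth(spec) |> rename(so2_percent = true_so2_percent)
cohort_ttests(meas) |> filter(region == "temporal")
#> # A tibble: 2 × 11
#>   kind   region   n_pairs mean_pre sd_pre mean_post sd_post mean_diff     t    df
#> 1 artery temporal      20     86.3   5.57      81.9    4.41      4.33  4.00    19
#> 2 vein   temporal      20     71.4   4.79      64.4    4.36      6.94  8.49    19
```

The occluded temporal vein drops ~7 percentage points one hour
post-occlusion (highly significant on a paired t-test with 19 df), the
artery ~4.4 points, while nasal control vessels show no significant
change.

A command-line wrapper (`inst/cli/retinox.R`) chains the same functions:
`simulate` writes ENVI-style cubes plus a ground-truth CSV, `oximetry`
writes per-animal measurements, `study` writes summary/t-test/AV tables,
`render` writes a pseudocolor PNG. All outputs carry provenance comment
headers and all randomness flows from `--seed`.

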