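# Synthetic hyperspectral fundus scenes.
#
# Forward model for a vessel pixel at wavelength lambda:
#   I(lambda) = I0(lambda) * 10^-( L * c * [s*eps_oxy + (1-s)*eps_deoxy]
#                                  + g(lambda) )
# with I0 = illumination * background reflectance, L the optical path in cm
# (path_length_scale * diameter), c total hemoglobin in mol/L, s the true
# oxygen saturation, and g(lambda) an additive scatter/offset term. The
# default g is constant + linear in lambda, i.e. inside the model class the
# unmixing fit uses, so noise-free inversion is exact; a wavelength
# power-law mode provides deliberate model mismatch for robustness tests.

#' Describe one vessel of a synthetic scene
#'
#' @param kind `"artery"` or `"vein"`.
#' @param region `"temporal"` or `"nasal"` (rabbit medullary-ray sides).
#' @param centerline Two-column matrix of (row, col) image points tracing
#'   the vessel centerline (1-based pixel coordinates).
#' @param diameter_um Vessel diameter in micrometers (>= 50 renderable at
#'   the default 10 um/pixel pitch).
#' @param true_so2 Ground-truth oxygen saturation, fraction in \[0, 1\].
#' @param hb_mol_l Total hemoglobin concentration in mol/L (tetramer);
#'   default 2.3e-3 corresponds to ~150 g/L whole blood.
#' @param path_length_scale Effective optical path as a multiple of the
#'   diameter (default 1, a single transit; double-pass and geometry
#'   effects fold into the fitted amplitude).
#' @return A one-row tibble (list-column `centerline`).
#' @export
vessel_spec <- function(kind = c("artery", "vein"),
                        region = c("temporal", "nasal"),
                        centerline,
                        diameter_um,
                        true_so2,
                        hb_mol_l = 2.3e-3,
                        path_length_scale = 1) {
  kind <- match.arg(kind)
  region <- match.arg(region)
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L ||
      any(!is.finite(centerline))) {
    abort("`centerline` must be a finite 2-column (row, col) matrix with >= 2 points")
  }
  if (!is.finite(diameter_um) || diameter_um <= 0) {
    abort("`diameter_um` must be positive")
  }
  if (!is.finite(true_so2) || true_so2 < 0 || true_so2 > 1) {
    abort("`true_so2` must lie in [0, 1]")
  }
  if (!is.finite(hb_mol_l) || hb_mol_l < 0) {
    abort("`hb_mol_l` must be >= 0")
  }
  tibble::tibble(
    kind = kind, region = region,
    centerline = list(unname(centerline)),
    diameter_um = diameter_um, true_so2 = true_so2,
    hb_mol_l = hb_mol_l, path_length_scale = path_length_scale
  )
}

#' Noise model for a synthetic scene
#'
#' @param kind `"none"`, `"gaussian"` (additive, per-band independent) or
#'   `"poisson"` (shot noise with detector gain).
#' @param sigma Gaussian standard deviation as a fraction of the
#'   illumination level (default 0.01, i.e. 1%).
#' @param gain Poisson gain: counts per photoelectron.
#' @return A list describing the noise model.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "poisson"),
                       sigma = 0.01, gain = 1) {
  kind <- match.arg(kind)
  list(kind = kind, sigma = sigma, gain = gain)
}

#' Describe a synthetic hyperspectral fundus scene
#'
#' @param n_rows,n_cols Image shape in pixels.
#' @param vessels Tibble of vessels, rows from [vessel_spec()].
#' @param pixel_pitch_um Pixel pitch in micrometers per pixel (default 10,
#'   so a 50 um vessel is 5 px wide).
#' @param background_reflectance Either a single reflectance in (0, 1] or a
#'   function of wavelength (nm) returning reflectances in (0, 1].
#' @param illumination Illumination level in arbitrary detector counts.
#' @param scatter Additive scatter/offset term of the vessel optical
#'   density: `list(mode = "linear", g0, g1)` gives
#'   `g(lambda) = g0 + g1 * (lambda - 575)`;
#'   `list(mode = "powerlaw", g0, b)` gives `g0 * (lambda/550)^-b`
#'   (outside the fit class, for model-mismatch tests);
#'   `list(mode = "none")` gives 0.
#' @param noise A [noise_spec()].
#' @param seed Integer seed used for the scene's noise draws.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_rows, n_cols, vessels = NULL,
                       pixel_pitch_um = 10,
                       background_reflectance = 0.6,
                       illumination = 10000,
                       scatter = list(mode = "linear", g0 = 0.08, g1 = 2e-4),
                       noise = noise_spec("none"),
                       seed = 1L) {
  if (!is.finite(n_rows) || !is.finite(n_cols) || n_rows < 1 || n_cols < 1) {
    abort("`n_rows` and `n_cols` must be positive")
  }
  if (is.numeric(background_reflectance)) {
    if (any(background_reflectance <= 0 | background_reflectance > 1)) {
      abort("`background_reflectance` must lie in (0, 1]")
    }
  } else if (!is.function(background_reflectance)) {
    abort("`background_reflectance` must be a number or a function of wavelength")
  }
  if (illumination <= 0) abort("`illumination` must be positive")
  if (is.null(vessels)) {
    vessels <- vessel_spec("artery", "temporal",
                           rbind(c(1, 1), c(1, 2)), 50, 0.5)[0, ]
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         vessels = vessels, pixel_pitch_um = pixel_pitch_um,
         background_reflectance = background_reflectance,
         illumination = illumination, scatter = scatter,
         noise = noise, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

scatter_term <- function(scatter, wl) {
  mode <- scatter$mode %||% "none"
  switch(mode,
    none = rep(0, length(wl)),
    linear = (scatter$g0 %||% 0) + (scatter$g1 %||% 0) * (wl - 575),
    powerlaw = (scatter$g0 %||% 0) * (wl / 550)^(-(scatter$b %||% 1)),
    abort(sprintf("unknown scatter mode '%s'", mode))
  )
}

background_at <- function(scene, wl) {
  r <- scene$background_reflectance
  r <- if (is.function(r)) r(wl) else rep(r, length.out = length(wl))
  if (any(r <= 0 | r > 1)) abort("background reflectance must lie in (0, 1]")
  r
}

# Pixels within half_width of the (row, col) polyline; logical matrix.
mask_from_centerline <- function(n_rows, n_cols, centerline, half_width) {
  rr <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
  d2 <- matrix(Inf, n_rows, n_cols)
  for (i in seq_len(nrow(centerline) - 1L)) {
    p <- centerline[i, ]; q <- centerline[i + 1L, ]
    v <- q - p
    vv <- sum(v * v)
    t <- if (vv == 0) 0 else pmin(1, pmax(0, ((rr - p[1]) * v[1] + (cc - p[2]) * v[2]) / vv))
    d2 <- pmin(d2, (rr - (p[1] + t * v[1]))^2 + (cc - (p[2] + t * v[2]))^2)
  }
  d2 <= half_width^2
}

# Per-band decadic absorbance of one vessel (length = length(wl)).
vessel_absorbance <- function(vessel, eps, scatter) {
  l_cm <- vessel$path_length_scale * vessel$diameter_um * 1e-4
  s <- vessel$true_so2
  l_cm * vessel$hb_mol_l *
    (s * eps$eps_oxy + (1 - s) * eps$eps_deoxy) +
    scatter_term(scatter, eps$wavelength_nm)
}

#' Render a synthetic scene into a hyperspectral cube
#'
#' Applies the modified Beer-Lambert forward model: background pixels carry
#' `illumination * reflectance(lambda)`; vessel pixels are attenuated by
#' `10^-OD(lambda)` with `OD = L*c*[s*eps_oxy + (1-s)*eps_deoxy] +
#' g(lambda)`. The returned cube's metadata records the vessel label image
#' and the per-vessel ground truth, so estimates can be scored against it.
#'
#' @param scene A [scene_spec()].
#' @param bands Wavelength grid (nm), e.g. [make_band_grid()].
#' @param extinction Extinction table, e.g. [hb_extinction()].
#' @return A `hyperspec_cube`.
#' @examples
#' sc <- rvo_scene()
#' cube <- render_cube(sc, make_band_grid(), hb_extinction())
#' dim(cube$intensities)
#' @export
render_cube <- function(scene, bands = make_band_grid(),
                        extinction = hb_extinction()) {
  stopifnot(inherits(scene, "scene_spec"))
  bands <- validate_bands(bands)
  eps <- resample_extinction(extinction, bands)
  nr <- scene$n_rows; nc <- scene$n_cols; nb <- length(bands)
  i0 <- scene$illumination * background_at(scene, bands)

  arr <- array(rep(i0, each = nr * nc), dim = c(nr, nc, nb))
  label <- matrix(0L, nr, nc)
  vessels <- scene$vessels
  occupied <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(vessels))) {
    v <- vessels[i, ]
    cl <- v$centerline[[1]]
    half_w <- v$diameter_um / scene$pixel_pitch_um / 2
    if (any(cl[, 1] < 1 - half_w) || any(cl[, 1] > nr + half_w) ||
        any(cl[, 2] < 1) || any(cl[, 2] > nc)) {
      abort(sprintf("vessel %d lies outside the %d x %d image", i, nr, nc))
    }
    mask <- mask_from_centerline(nr, nc, cl, half_w)
    if (!any(mask)) {
      abort(sprintf("vessel %d renders no pixels (diameter below pitch?)", i))
    }
    label[mask] <- i
    occupied <- occupied | mask
    atten <- 10^(-vessel_absorbance(v, eps, scene$scatter))
    idx <- which(mask)
    for (b in seq_len(nb)) {
      arr[idx + (b - 1L) * nr * nc] <- i0[b] * atten[b]
    }
  }

  if (scene$noise$kind != "none") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(scene$seed)
    if (scene$noise$kind == "gaussian") {
      arr <- arr + rnorm(length(arr), 0, scene$noise$sigma * scene$illumination)
      arr[arr < 0] <- 0
    } else {
      g <- scene$noise$gain
      arr <- array(rpois(length(arr), as.vector(arr) / g) * g, dim = dim(arr))
    }
  }

  truth <- if (nrow(vessels)) {
    tibble::tibble(
      vessel_id = seq_len(nrow(vessels)),
      kind = vessels$kind, region = vessels$region,
      diameter_um = vessels$diameter_um, true_so2 = vessels$true_so2,
      hb_mol_l = vessels$hb_mol_l,
      path_length_scale = vessels$path_length_scale
    )
  } else {
    tibble::tibble(vessel_id = integer(), kind = character(),
                   region = character(), diameter_um = numeric(),
                   true_so2 = numeric(), hb_mol_l = numeric(),
                   path_length_scale = numeric())
  }

  hyperspec_cube(arr, bands, metadata = list(
    label = label, truth = truth,
    illumination = scene$illumination,
    pixel_pitch_um = scene$pixel_pitch_um,
    scatter = scene$scatter, noise = scene$noise, seed = scene$seed
  ))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Construct a hyperspectral cube
#'
#' @param intensities Numeric array rows x cols x bands, finite and >= 0.
#' @param wavelengths Strictly increasing wavelengths (nm), one per band.
#' @param metadata Named list of acquisition/provenance key-values; for
#'   synthetic cubes this includes the vessel `label` image and `truth`.
#' @return A `hyperspec_cube` object.
#' @export
hyperspec_cube <- function(intensities, wavelengths, metadata = list()) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3-D array (rows x cols x bands)")
  }
  wavelengths <- validate_bands(wavelengths, "wavelengths")
  if (dim(intensities)[3] != length(wavelengths)) {
    abort("band axis length must equal the number of wavelengths")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    abort("intensities must be finite and >= 0")
  }
  structure(list(intensities = intensities, wavelengths = wavelengths,
                 metadata = metadata),
            class = "hyperspec_cube")
}

#' @export
print.hyperspec_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<hyperspec_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$metadata$truth) && nrow(x$metadata$truth)) {
    cat(sprintf("  synthetic: %d ground-truth vessels\n",
                nrow(x$metadata$truth)))
  }
  invisible(x)
}

#' Rabbit-like retinal vein occlusion scene preset
#'
#' Builds a medullary-ray scene: one horizontal vascularized streak with a
#' paired artery and vein on the temporal side and on the nasal side, the
#' layout of the rabbit retina where occlusions are induced temporally and
#' the nasal vessels serve as within-eye controls.
#'
#' @param so2 Named vector of ground-truth saturations (fractions) for
#'   `temporal_artery`, `temporal_vein`, `nasal_artery`, `nasal_vein`.
#' @param n_rows,n_cols Image shape (default 100 x 140 at 10 um/pixel).
#' @param artery_diameter_um,vein_diameter_um Vessel calibers; the default
#'   vein caliber (125 um) matches the laser spot sized to the rabbit
#'   retinal vein.
#' @param noise A [noise_spec()].
#' @param seed Scene seed for noise draws.
#' @param ... Passed on to [scene_spec()] (e.g. `scatter`, `illumination`).
#' @return A [scene_spec()].
#' @export
rvo_scene <- function(so2 = c(temporal_artery = 0.851, temporal_vein = 0.714,
                              nasal_artery = 0.852, nasal_vein = 0.692),
                      n_rows = 100, n_cols = 140,
                      artery_diameter_um = 75, vein_diameter_um = 125,
                      noise = noise_spec("none"), seed = 1L, ...) {
  need <- c("temporal_artery", "temporal_vein", "nasal_artery", "nasal_vein")
  if (!all(need %in% names(so2))) {
    abort(paste("`so2` must name:", paste(need, collapse = ", ")))
  }
  horiz <- function(row, c0, c1) rbind(c(row, c0), c(row, c1))
  vessels <- dplyr::bind_rows(
    vessel_spec("artery", "temporal", horiz(35, 11, 60),
                artery_diameter_um, so2[["temporal_artery"]]),
    vessel_spec("vein", "temporal", horiz(65, 11, 60),
                vein_diameter_um, so2[["temporal_vein"]]),
    vessel_spec("artery", "nasal", horiz(35, 81, 130),
                artery_diameter_um, so2[["nasal_artery"]]),
    vessel_spec("vein", "nasal", horiz(65, 81, 130),
                vein_diameter_um, so2[["nasal_vein"]])
  )
  scene_spec(n_rows, n_cols, vessels = vessels, noise = noise, seed = seed, ...)
}
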