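test_that("band grid has the documented default and exact endpoints", {
  b <- make_band_grid(450, 700, 76)
  expect_length(b, 76)
  expect_equal(b[1], 450)
  expect_equal(b[76], 700)
  expect_equal(unique(round(diff(b), 10)), round(250 / 75, 10))

  d <- 7.5
  expect_equal(make_band_grid(500, 500 + d, 2), c(500, 500 + d))
  expect_error(make_band_grid(700, 450, 10), "less than")
  expect_error(make_band_grid(450, 700, 1), ">= 2")
})

test_that("a vessel-free noise-free scene is background times illumination everywhere", {
  sc <- scene_spec(15, 20, background_reflectance = 0.55,
                   illumination = 5000)
  cube <- render_cube(sc, default_grid, hb_table)
  expect_equal(dim(cube$intensities), c(15L, 20L, 76L))
  for (b in c(1, 40, 76)) {
    expect_true(all(cube$intensities[, , b] == 5000 * 0.55))
  }
})

test_that("a bloodless vessel with zero scatter is indistinguishable from background", {
  sc <- single_vessel_scene(true_so2 = 0.5, hb_mol_l = 0,
                            scatter = list(mode = "none"))
  cube <- render_cube(sc, default_grid, hb_table)
  bg <- cube$intensities[1, 1, ]
  expect_true(all(apply(cube$intensities, 3, function(m) length(unique(as.vector(m)))) == 1))
  expect_equal(as.vector(cube$intensities[20, 30, ]), as.vector(bg))
})

test_that("noise-free vessel OD matches the closed-form forward exponent to 1e-9", {
  sc <- single_vessel_scene(true_so2 = 0.714)
  cube <- render_cube(sc, default_grid, hb_table)
  segs <- segments_from_truth(cube)
  od <- compute_od(cube, segs)
  expected <- analytic_od(sc$vessels[1, ], default_grid, hb_table)
  expect_lt(max(abs(od$od - expected)), 1e-9)
})

test_that("same seed gives bit-identical cubes; different seeds differ only by noise", {
  sc1 <- single_vessel_scene(noise = noise_spec("gaussian", 0.01), seed = 42L)
  sc2 <- single_vessel_scene(noise = noise_spec("gaussian", 0.01), seed = 42L)
  sc3 <- single_vessel_scene(noise = noise_spec("gaussian", 0.01), seed = 43L)
  c1 <- render_cube(sc1, default_grid)
  c2 <- render_cube(sc2, default_grid)
  c3 <- render_cube(sc3, default_grid)
  expect_identical(c1$intensities, c2$intensities)
  expect_false(identical(c1$intensities, c3$intensities))
  # noise-free parts agree: difference has noise scale, not structure
  expect_lt(max(abs(c1$intensities - c3$intensities)),
            10 * 0.01 * sc1$illumination)
})

test_that("attenuation is monotone: more absorber never increases intensity", {
  base <- single_vessel_scene(true_so2 = 0.7, hb_mol_l = 1.5e-3)
  more <- single_vessel_scene(true_so2 = 0.7, hb_mol_l = 2.5e-3)
  cb <- render_cube(base, default_grid)
  cm <- render_cube(more, default_grid)
  expect_true(all(cm$intensities <= cb$intensities + 1e-12))
  expect_true(all(cb$intensities > 0))
  expect_true(all(cb$intensities <= base$illumination))
})

test_that("doubling the path length doubles the absorbance part of the OD", {
  sc1 <- single_vessel_scene(true_so2 = 0.6, path_length_scale = 1,
                             scatter = list(mode = "none"))
  sc2 <- single_vessel_scene(true_so2 = 0.6, path_length_scale = 2,
                             scatter = list(mode = "none"))
  od1 <- compute_od(render_cube(sc1, default_grid),
                    segments_from_truth(render_cube(sc1, default_grid)))
  od2 <- compute_od(render_cube(sc2, default_grid),
                    segments_from_truth(render_cube(sc2, default_grid)))
  expect_equal(od2$od, 2 * od1$od, tolerance = 1e-9)
})

test_that("at an isosbestic wavelength the noise-free OD is independent of saturation", {
  iso <- isosbestic_wavelengths(hb_table)
  iso <- iso[iso >= 560 & iso <= 590][1]
  grid <- sort(c(make_band_grid(500, 600, 20), iso))
  ods <- sapply(c(0, 0.4, 0.8, 1), function(s) {
    sc <- single_vessel_scene(true_so2 = s)
    cube <- render_cube(sc, grid)
    od <- compute_od(cube, segments_from_truth(cube))
    od$od[od$wavelength_nm == iso]
  })
  expect_lt(diff(range(ods)), 1e-10)
})

test_that("vessels outside the image and bad backgrounds are rejected", {
  v <- vessel_spec("vein", "temporal", rbind(c(200, 5), c(200, 50)), 100, 0.5)
  sc <- scene_spec(40, 60, vessels = v)
  expect_error(render_cube(sc, default_grid), "outside")
  expect_error(scene_spec(40, 60, background_reflectance = 0), "\\(0, 1\\]")
  expect_error(scene_spec(40, 60, background_reflectance = 1.4), "\\(0, 1\\]")
})

test_that("cohort truth honours deltas, recannulation and degenerate sampling", {
  # zero deltas, fixed assignment: pre and post ground truth identical
  spec0 <- rvo_cohort_preset("laser-control-a", sampling = "fixed", seed = 5L)
  tr0 <- cohort_truth(spec0)
  wide <- tidyr::pivot_wider(tr0, names_from = timepoint,
                             values_from = true_so2_percent)
  expect_equal(wide$`1h`, wide$baseline, tolerance = 1e-12)

  # zero deltas, stochastic draws: arm means unchanged in expectation
  specn <- rvo_cohort_preset("laser-control-a", sampling = "normal", seed = 5L)
  specn$n_animals <- 2000L
  trn <- cohort_truth(specn)
  wn <- tidyr::pivot_wider(
    dplyr::filter(trn, kind == "vein", region == "temporal"),
    names_from = timepoint, values_from = true_so2_percent)
  expect_equal(mean(wn$`1h`), mean(wn$baseline), tolerance = 0.01)
  expect_gt(cor(wn$`1h`, wn$baseline), 0.5)

  # recannulation restores each animal's own baseline
  spec_r <- rvo_cohort_preset("recannulation", sampling = "normal", seed = 7L)
  tr <- cohort_truth(spec_r)
  wr <- tidyr::pivot_wider(tr, names_from = timepoint,
                           values_from = true_so2_percent)
  expect_equal(wr$`2wk`, wr$baseline, tolerance = 1e-12)
  vein1h <- dplyr::filter(tr, kind == "vein", region == "temporal",
                          timepoint == "1h")
  veinb <- dplyr::filter(tr, kind == "vein", region == "temporal",
                         timepoint == "baseline")
  expect_lt(mean(vein1h$true_so2_percent), mean(veinb$true_so2_percent))

  # fixed sampling: 20 identical pre/post truth pairs at the arm means
  specf <- rvo_cohort_preset("rvo-baseline", sampling = "fixed", seed = 1L)
  trf <- cohort_truth(specf)
  tv <- dplyr::filter(trf, kind == "vein", region == "temporal")
  expect_true(all(tv$true_so2_percent[tv$timepoint == "baseline"] == 71.4))
  expect_true(all(tv$true_so2_percent[tv$timepoint == "1h"] == 64.0))
  expect_equal(nrow(trf), 20L * 2L * 4L)

  # determinism
  expect_identical(cohort_truth(specf), cohort_truth(specf))
})

test_that("correlated follow-up draws keep arm means on the delta target", {
  spec <- rvo_cohort_preset("rvo-baseline", sampling = "normal", seed = 11L)
  spec$n_animals <- 4000L
  tr <- cohort_truth(spec)
  m <- dplyr::summarise(
    dplyr::group_by(tr, timepoint, kind, region),
    mu = mean(true_so2_percent), .groups = "drop")
  tv1h <- dplyr::filter(m, timepoint == "1h", kind == "vein",
                        region == "temporal")$mu
  expect_equal(tv1h, 64.0, tolerance = 0.5)
})
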