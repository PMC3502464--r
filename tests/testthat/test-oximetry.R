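test_that("wavelength selection returns 28 deterministic in-window bands with isosbestic anchors", {
  sel <- select_fit_wavelengths(default_grid, hb_table)
  expect_length(sel, 28)
  expect_true(all(sel %in% default_grid))
  expect_true(all(sel >= 500 & sel <= 600))
  expect_identical(sel, select_fit_wavelengths(default_grid, hb_table))

  # at least 2 near-isosbestic bands are present as amplitude anchors
  eps <- resample_extinction(hb_table, default_grid)
  d <- abs(eps$eps_oxy - eps$eps_deoxy)
  cand <- default_grid[default_grid >= 500 & default_grid <= 600]
  dc <- d[match(cand, default_grid)]
  anchors <- cand[order(dc)][1:2]
  expect_true(all(anchors %in% sel))

  # exhaustive selection returns every band
  all_sel <- select_fit_wavelengths(default_grid, hb_table,
                                    n = length(default_grid))
  expect_identical(all_sel, default_grid)
  expect_error(select_fit_wavelengths(default_grid, hb_table, n = 77),
               "cannot select")
})

test_that("pure and mixed analytic OD spectra give exact saturations", {
  wl <- select_fit_wavelengths(default_grid, hb_table)
  eps <- resample_extinction(hb_table, wl)
  model <- oximetry_model(fit_wavelengths = wl)

  f1 <- fit_so2(tibble::tibble(wavelength_nm = wl, od = 2e-3 * eps$eps_oxy),
                hb_table, model)
  expect_equal(f1$so2, 1.0, tolerance = 1e-10)
  expect_lt(f1$residual_norm, 1e-10)

  f0 <- fit_so2(tibble::tibble(wavelength_nm = wl, od = 2e-3 * eps$eps_deoxy),
                hb_table, model)
  expect_equal(f0$so2, 0.0, tolerance = 1e-10)
  expect_lt(f0$residual_norm, 1e-10)

  for (kappa in c(0.3, 1, 42)) {
    fm <- fit_so2(tibble::tibble(
      wavelength_nm = wl,
      od = kappa * 1e-3 * (0.5 * eps$eps_oxy + 0.5 * eps$eps_deoxy)),
      hb_table, model)
    expect_equal(fm$so2, 0.5, tolerance = 1e-10)
  }
})

test_that("estimates are invariant to OD amplitude and additive offsets", {
  sc <- single_vessel_scene(true_so2 = 0.63)
  cube <- render_cube(sc, default_grid)
  od <- compute_od(cube, segments_from_truth(cube))
  f <- fit_so2(od, hb_table)
  for (kappa in c(0.2, 5)) {
    fk <- fit_so2(dplyr::mutate(od, od = od * kappa), hb_table)
    expect_equal(fk$so2, f$so2, tolerance = 1e-9)
  }
  for (off in c(-0.3, 0.8)) {
    fo <- fit_so2(dplyr::mutate(od, od = od + off), hb_table)
    expect_equal(fo$so2, f$so2, tolerance = 1e-9)
  }
})

test_that("noise-free in-class forward data inverts exactly and monotonically", {
  s_true <- seq(0, 1, by = 0.1)
  s_hat <- sapply(s_true, function(s) {
    sc <- single_vessel_scene(true_so2 = s)
    cube <- render_cube(sc, default_grid)
    fit_so2(compute_od(cube, segments_from_truth(cube)), hb_table)$so2
  })
  expect_equal(s_hat[which.min(abs(s_true - 0.7))], 0.7, tolerance = 1e-6)
  expect_lt(max(abs(s_hat - s_true)), 1e-6)
  expect_true(all(diff(s_hat) > 0))
})

test_that("recovery at the study's venous saturation is exact to 1e-6", {
  sc <- single_vessel_scene(true_so2 = 0.714)
  cube <- render_cube(sc, default_grid)
  f <- fit_so2(compute_od(cube, segments_from_truth(cube)), hb_table)
  expect_equal(f$so2, 0.714, tolerance = 1e-6)
})

test_that("least-squares solution matches the normal-equations oracle to 1e-10", {
  wl <- c(506.7, 540, 560, 576.7, 586.7)
  eps <- resample_extinction(hb_table, wl)
  withr::with_seed(99, {
    for (rep in 1:20) {
      od_vals <- as.vector(
        cbind(eps$eps_oxy, eps$eps_deoxy, 1, (wl - 575) / 100) %*%
          c(runif(1, 1e-4, 3e-3), runif(1, 1e-4, 3e-3),
            rnorm(1, 0, 0.1), rnorm(1, 0, 0.05))) + rnorm(5, 0, 1e-3)
      x <- cbind(eps$eps_oxy, eps$eps_deoxy, 1, (wl - 575) / 100)
      oracle <- normal_equations_fit(x, od_vals)
      f <- fit_so2(tibble::tibble(wavelength_nm = wl, od = od_vals),
                   hb_table, oximetry_model(fit_wavelengths = wl))
      expect_equal(f$a_oxy, oracle[1], tolerance = 1e-10)
      expect_equal(f$b_deoxy, oracle[2], tolerance = 1e-10)
      expect_equal(f$so2_raw, oracle[1] / (oracle[1] + oracle[2]),
                   tolerance = 1e-10)
    }
  })
})

test_that("degenerate designs and non-positive hemoglobin amplitudes are flagged", {
  iso <- isosbestic_wavelengths(hb_table)
  iso <- iso[iso >= 500 & iso <= 600][1:3]
  expect_error(
    fit_so2(tibble::tibble(wavelength_nm = iso, od = c(0.1, 0.2, 0.3)),
            hb_table, oximetry_model(fit_wavelengths = iso,
                                     scatter = "const")),
    "degenerate")

  wl <- select_fit_wavelengths(default_grid, hb_table)
  eps <- resample_extinction(hb_table, wl)
  f <- fit_so2(tibble::tibble(wavelength_nm = wl, od = -2e-3 * eps$eps_oxy),
               hb_table, oximetry_model(fit_wavelengths = wl))
  expect_true(f$degenerate)
  expect_true(is.na(f$so2))
})

test_that("with 1% gaussian noise the mean absolute saturation error stays below 0.02", {
  s_grid <- rep(c(0.55, 0.64, 0.714, 0.851, 0.95), length.out = 200)
  errs <- sapply(seq_along(s_grid), function(i) {
    sc <- single_vessel_scene(true_so2 = s_grid[i],
                              noise = noise_spec("gaussian", 0.01),
                              seed = 1000L + i)
    cube <- render_cube(sc, default_grid)
    f <- fit_so2(compute_od(cube, segments_from_truth(cube)), hb_table)
    abs(f$so2 - s_grid[i])
  })
  expect_lte(mean(errs), 0.02)
})

test_that("tidy and glance expose coefficients and per-segment summaries", {
  sc <- rvo_scene()
  cube <- render_cube(sc, default_grid)
  f <- fit_so2(compute_od(cube, segments_from_truth(cube)), hb_table)
  td <- tidy(f)
  expect_setequal(unique(td$term),
                  c("a_oxy", "b_deoxy", "scatter_offset", "scatter_slope"))
  gl <- glance(f)
  expect_equal(nrow(gl), 4L)
  expect_true(all(gl$so2 >= 0 & gl$so2 <= 1))
})

test_that("saturation maps paint segment values over vessel pixels only", {
  v1 <- vessel_spec("artery", "temporal", rbind(c(15, 6), c(15, 55)), 80, 1.0)
  v2 <- vessel_spec("vein", "temporal", rbind(c(45, 6), c(45, 55)), 80, 0.0)
  sc <- scene_spec(60, 60, vessels = dplyr::bind_rows(v1, v2),
                   scatter = list(mode = "none"))
  cube <- render_cube(sc, default_grid)
  segs <- segments_from_truth(cube)
  m <- so2_map(cube, segs)
  vals <- sort(unique(round(as.vector(m$so2[!is.na(m$so2)]), 6)))
  expect_equal(vals, c(0, 1))
  expect_true(all(is.na(m$so2[cube$metadata$label == 0L])))

  m0 <- so2_map(cube, segs[0, ])
  expect_true(all(is.na(m0$so2)))

  mono <- so2_map(cube, segs[1, ])
  painted <- unique(round(mono$so2[!is.na(mono$so2)], 6))
  expect_length(painted, 1)
})
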