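test_that("detection finds a single straight vessel covering >=90% of the truth mask", {
  sc <- single_vessel_scene(true_so2 = 0.7)
  cube <- render_cube(sc, default_grid)
  segs <- detect_vessels(cube)
  expect_equal(nrow(segs), 1L)
  truth_px <- which(cube$metadata$label == 1L)
  found <- segs$vessel_px[[1]]
  found_lin <- found[, 1] + (found[, 2] - 1) * nrow(cube$metadata$label)
  expect_gte(length(intersect(found_lin, truth_px)) / length(truth_px), 0.9)
  expect_gt(nrow(segs$ref_px[[1]]), 0)
  # vessel and reference pixel sets are disjoint
  ref_lin <- segs$ref_px[[1]][, 1] +
    (segs$ref_px[[1]][, 2] - 1) * nrow(cube$metadata$label)
  expect_length(intersect(found_lin, ref_lin), 0)
})

test_that("a blank cube yields an empty segment list, not an error", {
  cube <- render_cube(scene_spec(20, 30), default_grid)
  segs <- detect_vessels(cube)
  expect_equal(nrow(segs), 0L)
})

test_that("two parallel vessels separated by more than 3 widths give 2 segments", {
  v1 <- vessel_spec("artery", "temporal", rbind(c(15, 6), c(15, 55)), 80, 0.9)
  v2 <- vessel_spec("vein", "temporal", rbind(c(45, 6), c(45, 55)), 80, 0.6)
  sc <- scene_spec(60, 60, vessels = dplyr::bind_rows(v1, v2))
  cube <- render_cube(sc, default_grid)
  segs <- detect_vessels(cube)
  expect_equal(nrow(segs), 2L)
  ann <- annotate_segments(segs, cube)
  expect_setequal(ann$kind, c("artery", "vein"))
})

test_that("truth segmentation returns one segment per label and validates references", {
  sc <- rvo_scene()
  cube <- render_cube(sc, default_grid)
  segs <- segments_from_truth(cube)
  expect_equal(nrow(segs), 4L)
  expect_setequal(segs$kind, c("artery", "vein"))
  expect_setequal(segs$region, c("temporal", "nasal"))

  # empty label image -> empty list
  blank <- render_cube(scene_spec(20, 30), default_grid)
  expect_equal(nrow(segments_from_truth(blank)), 0L)

  # labels covering the whole image -> no reference pixels -> error
  full <- blank
  full$metadata$label <- matrix(1L, 20, 30)
  expect_error(segments_from_truth(full), "reference")

  # missing labels -> configuration error
  nolab <- blank
  nolab$metadata$label <- NULL
  expect_error(segments_from_truth(nolab), "label")
})

test_that("OD definition: identity gives zero, a factor-10 dip gives OD 1", {
  cube <- render_cube(scene_spec(30, 40, background_reflectance = 0.5),
                      make_band_grid(500, 600, 5))
  # hand-built segment on a flat cube: OD must be exactly 0
  seg <- tibble::tibble(
    segment_id = 1L, kind = "vein", region = "temporal",
    width_px = 4, n_px = 40L,
    centerline = list(rbind(c(15, 5), c(15, 35))),
    vessel_px = list(as.matrix(expand.grid(14:16, 5:35))),
    core_px = list(as.matrix(expand.grid(15, 5:35))),
    ref_px = list(as.matrix(expand.grid(c(5, 25), 5:35)))
  )
  od <- compute_od(cube, seg)
  expect_true(all(od$od == 0))

  # dim the vessel core by exactly 10x at one band
  cube2 <- cube
  core <- seg$core_px[[1]]
  plane <- cube2$intensities[, , 3]
  plane[core] <- plane[core] / 10
  cube2$intensities[, , 3] <- plane
  od2 <- compute_od(cube2, seg)
  expect_equal(od2$od[3], 1.0)
  expect_true(all(od2$od[-3] == 0))
})

test_that("OD is invariant to a global illumination rescale", {
  sc <- single_vessel_scene(true_so2 = 0.65)
  cube <- render_cube(sc, default_grid)
  segs <- segments_from_truth(cube)
  od1 <- compute_od(cube, segs)
  cube_k <- cube
  cube_k$intensities <- cube$intensities * 3.7
  od2 <- compute_od(cube_k, segs)
  expect_equal(od2$od, od1$od, tolerance = 1e-12)
})

test_that("a zero vessel mean is capped with a warning; zero reference errors", {
  cube <- render_cube(scene_spec(30, 40), make_band_grid(500, 600, 4))
  seg <- tibble::tibble(
    segment_id = 1L, kind = "unknown", region = "unknown",
    width_px = 2, n_px = 31L,
    centerline = list(rbind(c(15, 5), c(15, 35))),
    vessel_px = list(as.matrix(expand.grid(15, 5:35))),
    core_px = list(as.matrix(expand.grid(15, 5:35))),
    ref_px = list(as.matrix(expand.grid(c(5, 25), 5:35)))
  )
  dark <- cube
  plane <- dark$intensities[, , 2]
  plane[seg$core_px[[1]]] <- 0
  dark$intensities[, , 2] <- plane
  expect_warning(od <- compute_od(dark, seg, od_cap = 6), "capped")
  expect_equal(od$od[2], 6)

  bad <- cube
  plane <- bad$intensities[, , 1]
  plane[seg$ref_px[[1]]] <- 0
  bad$intensities[, , 1] <- plane
  expect_error(compute_od(bad, seg), "reference")
})

test_that("detected and truth segmentations agree on OD within noise", {
  sc <- single_vessel_scene(true_so2 = 0.7,
                            noise = noise_spec("gaussian", 0.01), seed = 3L)
  cube <- render_cube(sc, default_grid)
  od_d <- compute_od(cube, detect_vessels(cube))
  od_t <- compute_od(cube, segments_from_truth(cube))
  expect_equal(nrow(od_d), nrow(od_t))
  expect_lt(median(abs(od_d$od - od_t$od)), 0.05)
})
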