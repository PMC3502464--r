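# Vessel segment extraction and optical-density spectra.
#
# Segments are located on a single high-contrast green band (hemoglobin
# absorbs strongly near 570 nm), then each segment's OD spectrum is the
# base-10 log ratio of a flanking background reference to the vessel core:
#   OD(lambda) = log10( mean I_ref(lambda) / mean I_vessel(lambda) )
# Robust (trimmed) means guard against stray pixels; the vessel core is
# the central 50% of the width to avoid edge partial-volume pixels.

# Geometry of one labelled component: principal-axis centerline, width,
# core (central half of the width) and flanking reference pixels offset
# ref_offset vessel widths to each side, excluding all vessel pixels.
segment_geometry <- function(pts, exclude_mask, n_rows, n_cols,
                             ref_offset = 2) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  cv <- crossprod(centered) / max(1, nrow(pts) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  u <- ev$vectors[, 1]                      # along-vessel axis
  nv <- c(-u[2], u[1])                      # unit normal
  t_coord <- centered %*% u
  p_coord <- centered %*% nv
  len <- diff(range(t_coord)) + 1
  width <- nrow(pts) / len
  core <- abs(p_coord - median(p_coord)) <= width / 4
  if (!any(core)) core <- rep(TRUE, nrow(pts))

  # centerline: mean position in ~10 bins along the axis
  nbin <- max(2L, min(10L, nrow(pts) %/% 4L))
  bins <- cut(t_coord, breaks = nbin, labels = FALSE)
  cl <- do.call(rbind, lapply(split(seq_len(nrow(pts)), bins), function(ix) {
    colMeans(pts[ix, , drop = FALSE])
  }))
  cl <- cl[order(cl %*% u), , drop = FALSE]

  ref <- NULL
  for (sgn in c(-1, 1)) {
    shift <- round(sgn * ref_offset * width * nv)
    cand <- sweep(pts, 2, shift, "+")
    keep <- cand[, 1] >= 1 & cand[, 1] <= n_rows &
      cand[, 2] >= 1 & cand[, 2] <= n_cols
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      free <- !exclude_mask[cand]
      ref <- rbind(ref, cand[free, , drop = FALSE])
    }
  }
  if (!is.null(ref)) ref <- unique(ref)
  list(width_px = width, centerline = unname(cl),
       vessel_px = unname(pts), core_px = unname(pts[core, , drop = FALSE]),
       ref_px = if (is.null(ref)) matrix(numeric(0), 0, 2) else unname(ref))
}

empty_segments <- function() {
  tibble::tibble(
    segment_id = integer(), kind = character(), region = character(),
    width_px = numeric(), n_px = integer(),
    centerline = list(), vessel_px = list(), core_px = list(),
    ref_px = list()
  )
}

segments_from_label <- function(label, truth = NULL, ref_offset = 2) {
  ids <- setdiff(sort(unique(as.integer(label))), 0L)
  if (!length(ids)) return(empty_segments())
  nr <- nrow(label); nc <- ncol(label)
  exclude <- grow_mask(label > 0L)
  rows <- purrr::map(ids, function(id) {
    pts <- which(label == id, arr.ind = TRUE)
    colnames(pts) <- NULL
    g <- segment_geometry(pts, exclude, nr, nc, ref_offset)
    if (nrow(g$ref_px) == 0L) {
      abort(sprintf(
        "no reference pixels available for segment %d (vessels cover the flanks)",
        id))
    }
    kind <- "unknown"; region <- "unknown"
    if (!is.null(truth)) {
      hit <- truth[truth$vessel_id == id, ]
      if (nrow(hit)) { kind <- hit$kind[1]; region <- hit$region[1] }
    }
    tibble::tibble(
      segment_id = id, kind = kind, region = region,
      width_px = g$width_px, n_px = nrow(pts),
      centerline = list(g$centerline), vessel_px = list(g$vessel_px),
      core_px = list(g$core_px), ref_px = list(g$ref_px)
    )
  })
  dplyr::bind_rows(rows)
}

# Binary mask grown by one pixel (3x3 box), used to keep reference pixels
# clear of vessel edges.
grow_mask <- function(mask) {
  m <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(3, "box"))
  as.matrix(m) > 0
}

#' Detect vessel segments on a single band
#'
#' Threshold detection on the band nearest `band_hint` (default ~570 nm,
#' where hemoglobin contrast against the fundus background is high):
#' pixels darker than `threshold` times the image median are labelled into
#' connected components; each sufficiently large component becomes a
#' segment with a principal-axis centerline, a width estimate, a core
#' pixel set (central 50% of the width), and flanking background reference
#' pixels offset `ref_offset` widths to each side. Deterministic.
#'
#' @param cube A `hyperspec_cube`.
#' @param band_hint Detection wavelength in nm; must lie within the cube's
#'   span.
#' @param threshold Fraction of the median image intensity below which a
#'   pixel counts as vessel.
#' @param min_px Minimum component size in pixels.
#' @param ref_offset Reference strip offset, in vessel widths.
#' @return Tibble of segments (possibly 0 rows) with list-columns
#'   `centerline`, `vessel_px`, `core_px`, `ref_px`. `kind`/`region` are
#'   `"unknown"`; see [annotate_segments()] to label them from ground
#'   truth.
#' @export
detect_vessels <- function(cube, band_hint = 570, threshold = 0.7,
                           min_px = 20L, ref_offset = 2) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  wl <- cube$wavelengths
  if (band_hint < min(wl) || band_hint > max(wl)) {
    abort(sprintf("`band_hint` %g nm outside cube span [%g, %g] nm",
                  band_hint, min(wl), max(wl)))
  }
  b <- which.min(abs(wl - band_hint))
  img <- cube$intensities[, , b]
  bg <- median(img)
  if (bg <= 0) return(empty_segments())
  binary <- img < threshold * bg
  if (!any(binary)) return(empty_segments())
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(binary * 1)))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_px])
  if (!length(keep)) return(empty_segments())
  lab[!(lab %in% keep)] <- 0L
  # renumber components 1..k in raster order of first appearance
  lab <- matrix(match(lab, c(0L, keep)) - 1L, nrow(lab), ncol(lab))
  segs <- segments_from_label(lab, truth = NULL, ref_offset = ref_offset)
  segs
}

#' Build segments from a cube's ground-truth label image
#'
#' Bypasses detection: segments are taken directly from the vessel label
#' image a synthetic cube carries in its metadata, with kind/region copied
#' from the ground truth. Reference pixels are flanking label-free strips.
#'
#' @inheritParams detect_vessels
#' @return Tibble of segments, one per labelled vessel.
#' @export
segments_from_truth <- function(cube, ref_offset = 2) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  label <- cube$metadata$label
  if (is.null(label)) {
    abort("cube metadata carries no label image; run detect_vessels() instead")
  }
  segments_from_label(label, truth = cube$metadata$truth,
                      ref_offset = ref_offset)
}

#' Label detected segments with ground-truth kind and region
#'
#' Assigns each detected segment the kind/region of the ground-truth
#' vessel its pixels overlap most (majority vote over the label image).
#' Segments overlapping no labelled vessel stay `"unknown"`.
#'
#' @param segments Segment tibble from [detect_vessels()].
#' @param cube The synthetic `hyperspec_cube` the segments came from.
#' @return `segments` with `kind`, `region` and a `true_so2` column filled
#'   from the metadata truth table.
#' @export
annotate_segments <- function(segments, cube) {
  label <- cube$metadata$label
  truth <- cube$metadata$truth
  if (is.null(label) || is.null(truth)) {
    abort("cube metadata carries no ground truth")
  }
  if (!nrow(segments)) {
    return(dplyr::mutate(segments, true_so2 = numeric(0)))
  }
  ann <- purrr::map(segments$vessel_px, function(px) {
    hits <- label[px]
    hits <- hits[hits > 0]
    if (!length(hits)) {
      return(tibble::tibble(kind = "unknown", region = "unknown",
                            true_so2 = NA_real_))
    }
    id <- as.integer(names(which.max(table(hits))))
    hit <- truth[truth$vessel_id == id, ]
    tibble::tibble(kind = hit$kind[1], region = hit$region[1],
                   true_so2 = hit$true_so2[1])
  })
  ann <- dplyr::bind_rows(ann)
  segments$kind <- ann$kind
  segments$region <- ann$region
  segments$true_so2 <- ann$true_so2
  segments
}

# n_px x n_bands matrix of spectra for a pixel set.
pixel_spectra <- function(cube, px) {
  d <- dim(cube$intensities)
  lin <- px[, 1] + (px[, 2] - 1) * d[1]
  idx <- outer(lin, (seq_len(d[3]) - 1L) * d[1] * d[2], "+")
  matrix(cube$intensities[idx], nrow = nrow(px), ncol = d[3])
}

#' Compute per-segment optical-density spectra
#'
#' For each segment and band, `OD = log10(mean_ref / mean_vessel)` using
#' `trim`-trimmed means of the reference pixels and of the vessel core
#' pixels. A zero vessel mean at some band is capped at `od_cap` with a
#' warning; a non-positive reference mean is an error naming the band.
#'
#' @param cube A `hyperspec_cube`.
#' @param segments Segment tibble from [detect_vessels()] or
#'   [segments_from_truth()].
#' @param trim Trim fraction for the robust means (default 0.1).
#' @param od_cap Cap substituted for infinite OD values.
#' @return Tibble with columns `segment_id`, `wavelength_nm`, `od`.
#' @export
compute_od <- function(cube, segments, trim = 0.1, od_cap = 6) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  wl <- cube$wavelengths
  if (!nrow(segments)) {
    return(tibble::tibble(segment_id = integer(), wavelength_nm = numeric(),
                          od = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    ref <- pixel_spectra(cube, segments$ref_px[[i]])
    ves <- pixel_spectra(cube, segments$core_px[[i]])
    ref_mean <- apply(ref, 2, mean, trim = trim)
    ves_mean <- apply(ves, 2, mean, trim = trim)
    if (any(ref_mean <= 0)) {
      abort(sprintf(
        "non-positive reference intensity for segment %d at %.1f nm",
        segments$segment_id[i], wl[which(ref_mean <= 0)[1]]))
    }
    od <- log10(ref_mean / ves_mean)
    if (any(!is.finite(od))) {
      warn(sprintf(
        "segment %d: infinite OD at %d band(s); capped at %g",
        segments$segment_id[i], sum(!is.finite(od)), od_cap))
      od[!is.finite(od)] <- od_cap
    }
    tibble::tibble(segment_id = segments$segment_id[i],
                   wavelength_nm = wl, od = od)
  })
}
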