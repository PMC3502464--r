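# Cube file formats and provenance-carrying CSVs.
#
# Primary dialect: ENVI-style — a small text header (<path>.hdr) plus raw
# band-sequential little-endian floats (<path>), the ubiquitous layout in
# hyperspectral tooling. Metadata (label image, ground truth, acquisition
# keys) travels in a JSON sidecar (<path>.meta.json). Default storage is
# 64-bit float so that write/read round-trips are bit-exact; 32-bit is
# available for compactness. Portability dialect: multi-page TIFF (one
# 32-bit page per band) with a wavelength sidecar CSV.

envi_hdr_path <- function(path) paste0(path, ".hdr")
meta_sidecar_path <- function(path) paste0(path, ".meta.json")
tiff_sidecar_path <- function(path) paste0(path, ".wavelengths.csv")

serialize_metadata <- function(metadata) {
  if (!is.null(metadata$label)) {
    metadata$label <- apply(metadata$label, 1, as.integer, simplify = FALSE)
  }
  jsonlite::toJSON(metadata, dataframe = "columns", digits = NA,
                   auto_unbox = TRUE, null = "null")
}

deserialize_metadata <- function(txt) {
  md <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.null(md$label)) {
    # serialized as a list of rows; fromJSON simplifies it back to a matrix
    md$label <- matrix(as.integer(md$label), nrow(md$label), ncol(md$label))
  }
  if (!is.null(md$truth)) md$truth <- tibble::as_tibble(md$truth)
  md
}

#' Write a hyperspectral cube to disk
#'
#' @param cube A `hyperspec_cube`.
#' @param path Output path. ENVI dialect writes `path` (raw binary),
#'   `path.hdr` (text header) and `path.meta.json` (metadata sidecar);
#'   TIFF dialect writes `path` (multi-page TIFF), `path.wavelengths.csv`
#'   and `path.meta.json`.
#' @param dialect `"envi"` (band-sequential raw floats, default) or
#'   `"tiff"` (one 32-bit float page per band, intensities stored scaled
#'   to \[0, 1\] with the scale recorded in the sidecar).
#' @param data_type ENVI sample format: `"float64"` (lossless round trip,
#'   default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "tiff"),
                       data_type = c("float64", "float32")) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  dialect <- match.arg(dialect)
  data_type <- match.arg(data_type)
  d <- dim(cube$intensities)

  if (dialect == "envi") {
    size <- if (data_type == "float64") 8L else 4L
    hdr <- c(
      "ENVI",
      sprintf("samples = %d", d[2]),
      sprintf("lines = %d", d[1]),
      sprintf("bands = %d", d[3]),
      sprintf("data type = %d", if (size == 8L) 5L else 4L),
      "interleave = bsq",
      "byte order = 0",
      paste0("wavelength = { ",
             paste(format(cube$wavelengths, digits = 17, trim = TRUE),
                   collapse = ", "), " }")
    )
    writeLines(hdr, envi_hdr_path(path))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    # BSQ: each band stored row-major (lines of samples)
    for (b in seq_len(d[3])) {
      writeBin(as.vector(t(cube$intensities[, , b])), con,
               size = size, endian = "little")
    }
  } else {
    scale <- max(cube$intensities, 1e-12)
    pages <- lapply(seq_len(d[3]), function(b) cube$intensities[, , b] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    readr::write_csv(tibble::tibble(band = seq_len(d[3]),
                                    wavelength_nm = cube$wavelengths,
                                    intensity_scale = scale),
                     tiff_sidecar_path(path))
  }
  writeLines(serialize_metadata(cube$metadata), meta_sidecar_path(path))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?m)^", key, "\\s*=\\s*(\\S+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) abort(sprintf("ENVI header missing field '%s'", key))
    as.numeric(m[2])
  }
  wl_m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl_m) < 2) abort("ENVI header missing field 'wavelength'")
  wl <- as.numeric(strsplit(wl_m[2], ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       wavelengths = wl)
}

#' Read a hyperspectral cube from disk
#'
#' @inheritParams write_cube
#' @return A `hyperspec_cube`.
#' @export
read_cube <- function(path, dialect = c("envi", "tiff")) {
  dialect <- match.arg(dialect)
  md <- list()
  if (file.exists(meta_sidecar_path(path))) {
    md <- deserialize_metadata(
      paste(readLines(meta_sidecar_path(path)), collapse = "\n"))
  }
  if (dialect == "envi") {
    if (!file.exists(envi_hdr_path(path))) {
      abort(sprintf("ENVI header not found at '%s'", envi_hdr_path(path)))
    }
    h <- parse_envi_header(envi_hdr_path(path))
    if (length(h$wavelengths) != h$bands) {
      abort(sprintf(
        "header declares %d bands but lists %d wavelengths",
        h$bands, length(h$wavelengths)))
    }
    if (!h$data_type %in% c(4, 5)) {
      abort(sprintf("unsupported ENVI data type %d (expect 4 or 5)",
                    h$data_type))
    }
    size <- if (h$data_type == 5) 8L else 4L
    n <- h$samples * h$lines * h$bands
    expected <- n * size
    if (file.size(path) < expected) {
      abort(sprintf(
        "binary file truncated: %d bytes, header implies %d",
        file.size(path), expected))
    }
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    vals <- readBin(con, "double", n = n, size = size, endian = "little")
    arr <- array(NA_real_, dim = c(h$lines, h$samples, h$bands))
    per_band <- h$lines * h$samples
    for (b in seq_len(h$bands)) {
      arr[, , b] <- t(matrix(vals[((b - 1) * per_band + 1):(b * per_band)],
                             nrow = h$samples))
    }
    hyperspec_cube(arr, h$wavelengths, md)
  } else {
    if (!file.exists(tiff_sidecar_path(path))) {
      abort(sprintf(
        "wavelength sidecar not found; expected band wavelengths at '%s'",
        tiff_sidecar_path(path)))
    }
    side <- readr::read_csv(tiff_sidecar_path(path),
                            show_col_types = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != nrow(side)) {
      abort(sprintf("TIFF has %d pages but sidecar lists %d wavelengths",
                    length(pages), nrow(side)))
    }
    scale <- side$intensity_scale[1] %||% 1
    arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
    for (b in seq_along(pages)) arr[, , b] <- pages[[b]] * scale
    hyperspec_cube(arr, side$wavelength_nm, md)
  }
}

#' Linear blue-to-red saturation colormap
#'
#' Maps saturation 0 to pure blue, 1 to pure red, linearly in between
#' (0.5 is the exact midpoint, half red half blue).
#'
#' @param v Saturations in \[0, 1\] (values outside are clipped).
#' @return Matrix with columns r, g, b in \[0, 1\].
#' @export
so2_colormap <- function(v) {
  v <- pmin(1, pmax(0, v))
  cbind(r = v, g = rep(0, length(v)), b = 1 - v)
}

#' Render a pseudocolor saturation map to PNG
#'
#' Vessel pixels are colored by the linear blue-to-red map (red = 100%
#' saturation, blue = 0%); non-vessel (sentinel) pixels show the
#' underlying grayscale band; a vertical color bar legend is appended on
#' the right.
#'
#' @param map An `so2_map` from [so2_map()].
#' @param path Output PNG path.
#' @param legend_width Width of the color bar block in pixels (0 disables).
#' @return `path`, invisibly.
#' @export
render_pseudocolor <- function(map, path, legend_width = 12L) {
  stopifnot(inherits(map, "so2_map"))
  nr <- nrow(map$so2); nc <- ncol(map$so2)
  rgb <- array(0, dim = c(nr, nc, 3))
  for (k in 1:3) rgb[, , k] <- map$underlay
  sel <- which(!is.na(map$so2))
  if (length(sel)) {
    cols <- so2_colormap(map$so2[sel])
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[sel] <- cols[, k]
      rgb[, , k] <- plane
    }
  }
  if (legend_width > 0) {
    ramp <- so2_colormap(seq(1, 0, length.out = nr))
    legend <- array(0, dim = c(nr, legend_width, 3))
    for (k in 1:3) legend[, , k] <- matrix(ramp[, k], nr, legend_width)
    out <- array(0, dim = c(nr, nc + legend_width + 2L, 3))
    out[, seq_len(nc), ] <- rgb
    out[, nc + 1:2, ] <- 1  # white gutter
    out[, (nc + 3):(nc + 2 + legend_width), ] <- legend
    rgb <- out
  }
  png::writePNG(rgb, path)
  invisible(path)
}
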