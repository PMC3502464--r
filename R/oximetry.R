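# Least-squares hemoglobin unmixing of vessel OD spectra.
#
# Modified Beer-Lambert model, linear in its coefficients:
#   OD(lambda) ~ a * eps_oxy(lambda) + b * eps_deoxy(lambda) + scatter(lambda)
# with scatter either a constant or constant + linear-in-lambda. The
# saturation estimate is the coefficient ratio s = a / (a + b), which makes
# it invariant to the overall OD amplitude (path length, hematocrit) and,
# with the constant scatter column, to any additive OD offset.

#' Oximetry model configuration
#'
#' @param fit_wavelengths Optional numeric vector of wavelengths (nm) to
#'   fit at; when `NULL` they are chosen by [select_fit_wavelengths()] from
#'   the OD spectrum's own bands (default 28 wavelengths).
#' @param n_fit Number of fit wavelengths when selecting automatically.
#' @param scatter Scatter term of the linear design: `"linear"` (constant +
#'   linear-in-wavelength, the default) or `"const"`.
#' @param clip Clip the saturation estimate to \[0, 1\] (flagged in the
#'   result) rather than reporting raw ratios only.
#' @param selection_window Wavelength window (nm) the automatic selection
#'   draws from.
#' @param n_isosbestic Number of near-isosbestic anchor bands the
#'   selection must include.
#' @return An `oximetry_model` list.
#' @export
oximetry_model <- function(fit_wavelengths = NULL, n_fit = 28L,
                           scatter = c("linear", "const"),
                           clip = TRUE,
                           selection_window = c(500, 600),
                           n_isosbestic = 2L) {
  scatter <- match.arg(scatter)
  if (!is.null(fit_wavelengths)) {
    fit_wavelengths <- validate_bands(fit_wavelengths, "fit_wavelengths")
    if (length(fit_wavelengths) < 3L) {
      abort("`fit_wavelengths` must contain at least 3 wavelengths")
    }
  }
  structure(list(fit_wavelengths = fit_wavelengths, n_fit = as.integer(n_fit),
                 scatter = scatter, clip = clip,
                 selection_window = selection_window,
                 n_isosbestic = as.integer(n_isosbestic)),
            class = "oximetry_model")
}

#' Select fit wavelengths from a band grid
#'
#' Deterministic selection of `n` bands for the unmixing fit: from the
#' candidate bands inside `window` (falling back to all bands if the
#' window holds fewer than `n`), take the `n_isosbestic` bands with the
#' smallest |eps_oxy - eps_deoxy| as amplitude anchors, then fill with the
#' bands of largest |eps_oxy - eps_deoxy| (most saturation-discriminating).
#' Ties break toward shorter wavelengths. The default count is 28.
#'
#' @param bands Cube band grid (nm).
#' @param extinction Extinction table.
#' @param n Number of wavelengths to select (3 <= n <= length(bands)).
#' @param window Selection window in nm.
#' @param n_isosbestic Number of near-isosbestic anchors to include.
#' @return Increasing numeric vector of `n` wavelengths, a subset of
#'   `bands`.
#' @export
select_fit_wavelengths <- function(bands, extinction = hb_extinction(),
                                   n = 28L, window = c(500, 600),
                                   n_isosbestic = 2L) {
  bands <- validate_bands(bands)
  if (n > length(bands)) {
    abort(sprintf("cannot select %d wavelengths from %d bands",
                  n, length(bands)))
  }
  if (n < 3L) abort("`n` must be >= 3")
  eps <- resample_extinction(extinction, bands)
  cand <- which(bands >= window[1] & bands <= window[2])
  if (length(cand) < n) cand <- seq_along(bands)
  d <- abs(eps$eps_oxy - eps$eps_deoxy)[cand]
  # order() is stable, so ties resolve toward shorter wavelengths
  n_iso <- min(n_isosbestic, n)
  anchors <- cand[order(d)][seq_len(n_iso)]
  rest <- setdiff(cand[order(-d)], anchors)
  sel <- sort(c(anchors, rest[seq_len(n - length(anchors))]))
  bands[sel]
}

scatter_columns <- function(wl, scatter) {
  if (scatter == "const") {
    m <- cbind(offset = rep(1, length(wl)))
  } else {
    m <- cbind(offset = rep(1, length(wl)), slope = (wl - 575) / 100)
  }
  m
}

fit_one_od <- function(wl, od, eps, model) {
  x <- cbind(eps_oxy = eps$eps_oxy, eps_deoxy = eps$eps_deoxy,
             scatter_columns(wl, model$scatter))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    abort("degenerate unmixing design (fit wavelengths do not separate oxy- from deoxyhemoglobin)")
  }
  beta <- qr.coef(qx, od)
  res <- od - as.vector(x %*% beta)
  a <- beta[["eps_oxy"]]; b <- beta[["eps_deoxy"]]
  degenerate <- (a + b) <= 0
  raw <- if (degenerate) NA_real_ else a / (a + b)
  clipped <- FALSE
  so2 <- raw
  if (!degenerate && model$clip && (raw < 0 || raw > 1)) {
    clipped <- TRUE
    so2 <- min(1, max(0, raw))
  }
  tibble::tibble(
    so2 = so2, so2_raw = raw, a_oxy = a, b_deoxy = b,
    scatter_offset = beta[["offset"]],
    scatter_slope = if (model$scatter == "linear") beta[["slope"]] else NA_real_,
    residual_norm = sqrt(sum(res^2)), n_wavelengths = length(wl),
    clipped = clipped, degenerate = degenerate
  )
}

#' Estimate oxygen saturation from OD spectra
#'
#' Solves the linear least-squares unmixing problem at the model's fit
#' wavelengths for each segment in `od` and reports the saturation
#' estimate `so2 = a/(a + b)` with fit diagnostics. A result is flagged
#' `degenerate` (saturation `NA`) when the total hemoglobin amplitude
#' `a + b` is not positive; estimates outside \[0, 1\] are clipped and
#' flagged when the model's clipping policy is on.
#'
#' @param od OD tibble from [compute_od()] (columns `wavelength_nm`, `od`,
#'   optional `segment_id`).
#' @param extinction Extinction table.
#' @param model An [oximetry_model()].
#' @return An `oximetry_fit` tibble, one row per segment: `so2` (fraction),
#'   `so2_percent`, coefficients, `residual_norm`, `clipped`, `degenerate`.
#' @examples
#' bands <- make_band_grid()
#' cube <- render_cube(rvo_scene(), bands)
#' segs <- segments_from_truth(cube)
#' fit_so2(compute_od(cube, segs))
#' @export
fit_so2 <- function(od, extinction = hb_extinction(),
                    model = oximetry_model()) {
  stopifnot(inherits(model, "oximetry_model"))
  if (!all(c("wavelength_nm", "od") %in% names(od))) {
    abort("`od` must have columns wavelength_nm and od")
  }
  if (!"segment_id" %in% names(od)) od$segment_id <- 1L

  groups <- split(od, od$segment_id)
  out <- purrr::map_dfr(groups, function(g) {
    g <- g[order(g$wavelength_nm), ]
    fit_wl <- model$fit_wavelengths
    if (is.null(fit_wl)) {
      fit_wl <- select_fit_wavelengths(
        sort(unique(g$wavelength_nm)), extinction,
        n = min(model$n_fit, length(unique(g$wavelength_nm))),
        window = model$selection_window,
        n_isosbestic = model$n_isosbestic)
    }
    idx <- match(round(fit_wl, 6), round(g$wavelength_nm, 6))
    if (any(is.na(idx))) {
      abort(sprintf("OD spectrum does not cover fit wavelength %.3f nm",
                    fit_wl[which(is.na(idx))[1]]))
    }
    eps <- resample_extinction(extinction, fit_wl)
    res <- fit_one_od(fit_wl, g$od[idx], eps, model)
    res$segment_id <- g$segment_id[1]
    res
  })
  out <- dplyr::relocate(out, "segment_id")
  out$so2_percent <- out$so2 * 100
  out <- dplyr::relocate(out, "so2_percent", .after = "so2")
  class(out) <- c("oximetry_fit", class(out))
  attr(out, "model") <- model
  out
}

#' @method tidy oximetry_fit
#' @export
tidy.oximetry_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("segment_id", "a_oxy", "b_deoxy",
                             "scatter_offset", "scatter_slope")],
    -"segment_id", names_to = "term", values_to = "estimate")
  dplyr::filter(long, !is.na(.data$estimate))
}

#' @method glance oximetry_fit
#' @export
glance.oximetry_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("segment_id", "so2", "so2_percent",
                           "residual_norm", "n_wavelengths",
                           "clipped", "degenerate")]
}

#' Paint a per-segment saturation map
#'
#' Assigns each segment's fitted saturation to all of its vessel pixels
#' (the default, matching per-vessel reporting); optionally fits every
#' vessel pixel's own OD spectrum (`per_pixel = TRUE`, slower). Non-vessel
#' pixels carry `NA`. A fit failure in one segment is logged and leaves
#' its pixels `NA` without aborting the others.
#'
#' @param cube A `hyperspec_cube`.
#' @param segments Segment tibble.
#' @param extinction Extinction table.
#' @param model An [oximetry_model()].
#' @param per_pixel Fit each vessel pixel separately.
#' @param trim Trim fraction passed to [compute_od()].
#' @return An `so2_map`: list with the saturation matrix `so2`, a
#'   normalized grayscale `underlay` (band nearest 570 nm) and its
#'   wavelength.
#' @export
so2_map <- function(cube, segments, extinction = hb_extinction(),
                    model = oximetry_model(), per_pixel = FALSE,
                    trim = 0.1) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  d <- dim(cube$intensities)
  vals <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    ok <- tryCatch({
      if (per_pixel) {
        ref <- pixel_spectra(cube, seg$ref_px[[1]])
        ref_mean <- apply(ref, 2, mean, trim = trim)
        ves <- pixel_spectra(cube, seg$vessel_px[[1]])
        for (p in seq_len(nrow(ves))) {
          od_p <- tibble::tibble(wavelength_nm = cube$wavelengths,
                                 od = log10(ref_mean / ves[p, ]))
          od_p <- od_p[is.finite(od_p$od), ]
          fit <- fit_so2(od_p, extinction, model)
          vals[seg$vessel_px[[1]][p, , drop = FALSE]] <- fit$so2
        }
      } else {
        od <- compute_od(cube, seg, trim = trim)
        fit <- fit_so2(od, extinction, model)
        vals[seg$vessel_px[[1]]] <- fit$so2
      }
      TRUE
    }, error = function(e) {
      warn(sprintf("segment %d: %s", seg$segment_id, conditionMessage(e)))
      FALSE
    })
    invisible(ok)
  }
  b <- which.min(abs(cube$wavelengths - 570))
  under <- cube$intensities[, , b]
  rng <- range(under)
  under <- if (diff(rng) > 0) (under - rng[1]) / diff(rng) else under * 0
  structure(list(so2 = vals, underlay = under,
                 underlay_wavelength = cube$wavelengths[b]),
            class = "so2_map")
}

#' @export
print.so2_map <- function(x, ...) {
  n <- sum(!is.na(x$so2))
  cat(sprintf("<so2_map> %d x %d, %d vessel pixels",
              nrow(x$so2), ncol(x$so2), n))
  if (n) cat(sprintf(", so2 range %.3f-%.3f",
                     min(x$so2, na.rm = TRUE), max(x$so2, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}
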