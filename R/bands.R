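#' Build an evenly spaced spectral band grid
#'
#' The imaging default is 76 bands spanning 450-700 nm (about 3.3 nm
#' spacing), matching a snapshot hyperspectral fundus acquisition.
#'
#' @param lambda_min,lambda_max Grid endpoints in nm (`lambda_min <
#'   lambda_max`); both are included in the grid.
#' @param n_bands Number of bands (>= 2).
#' @return Numeric vector of `n_bands` strictly increasing wavelengths.
#' @examples
#' b <- make_band_grid()
#' length(b); range(b)
#' @export
make_band_grid <- function(lambda_min = 450, lambda_max = 700, n_bands = 76) {
  if (!is.numeric(lambda_min) || !is.numeric(lambda_max) ||
      length(lambda_min) != 1L || length(lambda_max) != 1L ||
      !is.finite(lambda_min) || !is.finite(lambda_max) ||
      lambda_min >= lambda_max) {
    abort("`lambda_min` must be a finite number less than `lambda_max`")
  }
  if (!is.numeric(n_bands) || length(n_bands) != 1L || !is.finite(n_bands) ||
      n_bands < 2 || n_bands != round(n_bands)) {
    abort("`n_bands` must be an integer >= 2")
  }
  seq(lambda_min, lambda_max, length.out = as.integer(n_bands))
}

validate_bands <- function(bands, arg = "bands") {
  if (!is.numeric(bands) || length(bands) < 1L || any(!is.finite(bands))) {
    abort(paste0("`", arg, "` must be a finite numeric vector"))
  }
  if (length(bands) > 1L && any(diff(bands) <= 0)) {
    abort(paste0("`", arg, "` must be strictly increasing"))
  }
  as.numeric(bands)
}
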