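# ggplot2 displays for the main result types.

#' Plot extinction spectra
#'
#' @param table An extinction table.
#' @return A ggplot.
#' @export
plot_extinction <- function(table = hb_extinction()) {
  long <- tidyr::pivot_longer(table, c("eps_oxy", "eps_deoxy"),
                              names_to = "species", values_to = "epsilon")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$epsilon,
                                     color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(eps_oxy = "#d62728", eps_deoxy = "#1f77b4"),
      labels = c(eps_oxy = "HbO2", eps_deoxy = "Hb")) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(epsilon ~ (cm^-1 ~ M^-1)),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot OD spectra per segment
#'
#' @param od OD tibble from [compute_od()].
#' @return A ggplot.
#' @export
plot_od_spectra <- function(od) {
  ggplot2::ggplot(od, ggplot2::aes(.data$wavelength_nm, .data$od,
                                   group = .data$segment_id,
                                   color = factor(.data$segment_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "optical density",
                  color = "segment") +
    ggplot2::theme_minimal()
}

#' @method autoplot so2_map
#' @export
autoplot.so2_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$so2)), times = ncol(object$so2)),
    col = rep(seq_len(ncol(object$so2)), each = nrow(object$so2)),
    so2 = as.vector(object$so2),
    underlay = as.vector(object$underlay)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$underlay),
                         fill = "grey30") +
    ggplot2::geom_raster(data = df[!is.na(df$so2), ],
                         ggplot2::aes(fill = .data$so2)) +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), name = "SO2") +
    ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @method autoplot oximetry_fit
#' @export
autoplot.oximetry_fit <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$segment_id),
                                   .data$so2_percent)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$so2), width = 0.7) +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::labs(x = "segment", y = "estimated SO2 (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Pre/post bar summary of cohort arms
#'
#' Mean +/- SD bars per (region, kind) arm and timepoint, the layout of
#' the study's cohort summaries.
#'
#' @param summary Tibble from [summarize_arms()].
#' @return A ggplot.
#' @export
plot_cohort_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$timepoint, .data$mean_percent,
                               fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent - .data$sd_percent,
                   ymax = .data$mean_percent + .data$sd_percent),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_manual(values = c(artery = "#d62728",
                                          vein = "#1f77b4")) +
    ggplot2::labs(x = NULL, y = "SO2 (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
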