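# Cohort statistics: per-arm mean +/- SD summaries, paired two-tailed
# t-tests of pre vs. post saturations, and arteriovenous differences.
# Saturations are on the percent scale (0-100) throughout this module.

#' Paired two-tailed t-test on pre/post saturations
#'
#' Tests the elementwise differences `pre - post` with Student's paired,
#' two-tailed t-test (df = n - 1). Degenerate inputs are handled
#' explicitly: all-identical pairs give t = 0, p = 1; a zero-variance
#' nonzero difference gives a p = 0 sentinel with a warning.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2), paired by
#'   animal, in percent.
#' @return One-row tibble: `n_pairs`, `mean_pre`, `sd_pre`, `mean_post`,
#'   `sd_post`, `mean_diff`, `t`, `df`, `p_value`.
#' @examples
#' paired_ttest(c(71, 73, 70), c(70, 71, 67))
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length")
  }
  n <- length(pre)
  if (n < 2L) abort("paired test needs at least 2 pairs")
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    abort("`pre` and `post` must be finite")
  }
  d <- pre - post
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      warn("all paired differences identical and nonzero; p reported as 0")
      tt <- list(statistic = sign(mean(d)) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(pre, post, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  tibble::tibble(
    n_pairs = n,
    mean_pre = mean(pre), sd_pre = sd(pre),
    mean_post = mean(post), sd_post = sd(post),
    mean_diff = mean(d),
    t = unname(tt$statistic), df = n - 1L, p_value = tt$p.value
  )
}

validate_measurements <- function(data, arg = "data") {
  need <- c("animal", "timepoint", "kind", "region", "so2_percent")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort(paste0("`", arg, "` must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(data$so2_percent < 0 | data$so2_percent > 100, na.rm = TRUE)) {
    abort("`so2_percent` must lie in [0, 100]")
  }
  invisible(data)
}

#' Per-arm mean +/- SD summary of cohort measurements
#'
#' Groups measurements by (timepoint, kind, region) and reports n, mean
#' and SD of the saturations, the layout of the study's pre/post bar
#' summaries. Groups of a single animal get SD 0 with a flag.
#'
#' @param data Measurements tibble: `animal`, `timepoint`, `kind`,
#'   `region`, `so2_percent`.
#' @return Tibble: `timepoint`, `kind`, `region`, `n`, `mean_percent`,
#'   `sd_percent`, `single_animal`.
#' @export
summarize_arms <- function(data) {
  validate_measurements(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$timepoint, .data$kind, .data$region),
    n = dplyr::n(),
    mean_percent = mean(.data$so2_percent),
    sd_percent = ifelse(dplyr::n() > 1, sd(.data$so2_percent), 0),
    single_animal = dplyr::n() == 1L,
    .groups = "drop"
  )
}

#' Paired pre/post t-tests for every arm of a cohort
#'
#' For each (kind, region) arm, pairs each animal's baseline measurement
#' with its measurement at `post`, and runs [paired_ttest()]. Animals
#' missing either timepoint are dropped from that arm with a warning.
#'
#' @param data Measurements tibble (see [summarize_arms()]).
#' @param baseline,post Timepoint labels to compare.
#' @return Tibble with one row per arm: `kind`, `region` plus the
#'   [paired_ttest()] columns.
#' @export
cohort_ttests <- function(data, baseline = "baseline", post = "1h") {
  validate_measurements(data)
  wide <- tidyr::pivot_wider(
    dplyr::filter(data, .data$timepoint %in% c(baseline, post)),
    id_cols = c("animal", "kind", "region"),
    names_from = "timepoint", values_from = "so2_percent")
  if (!all(c(baseline, post) %in% names(wide))) {
    abort(sprintf("timepoints '%s' and '%s' not both present", baseline, post))
  }
  incomplete <- is.na(wide[[baseline]]) | is.na(wide[[post]])
  if (any(incomplete)) {
    warn(sprintf("%d animal/arm pairs missing a timepoint; dropped",
                 sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  dplyr::reframe(
    dplyr::group_by(wide, .data$kind, .data$region),
    paired_ttest(.data[[baseline]], .data[[post]])
  )
}

#' Arteriovenous saturation differences
#'
#' Computes AV = artery% - vein% per animal, timepoint and region (a proxy
#' for tissue oxygen extraction). Units missing either vessel are skipped
#' with a warning. With `summarize = TRUE` returns arm means instead of
#' per-animal rows.
#'
#' @param data Measurements tibble (see [summarize_arms()]).
#' @param summarize Return per-(timepoint, region) means of the AV
#'   difference instead of per-animal rows.
#' @return Tibble: `animal`, `timepoint`, `region`, `av_percent` (or the
#'   arm-mean version).
#' @export
av_difference <- function(data, summarize = FALSE) {
  validate_measurements(data)
  wide <- tidyr::pivot_wider(
    data, id_cols = c("animal", "timepoint", "region"),
    names_from = "kind", values_from = "so2_percent")
  for (col in c("artery", "vein")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  bad <- is.na(wide$artery) | is.na(wide$vein)
  if (any(bad)) {
    warn(sprintf("%d unit(s) missing an artery or vein row; skipped",
                 sum(bad)))
    wide <- wide[!bad, ]
  }
  out <- dplyr::transmute(wide, .data$animal, .data$timepoint, .data$region,
                          av_percent = .data$artery - .data$vein)
  if (summarize) {
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$timepoint, .data$region),
      n = dplyr::n(), mean_av_percent = mean(.data$av_percent),
      sd_av_percent = ifelse(dplyr::n() > 1, sd(.data$av_percent), 0),
      .groups = "drop")
  }
  out
}
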