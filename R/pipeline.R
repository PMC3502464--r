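# End-to-end pipeline: cohort scenes -> cubes -> segments -> OD -> fitted
# saturations -> per-animal measurements, plus config-driven runners
# (simulate / oximetry / study / render) used by the command-line wrapper.
# Every output CSV carries provenance (package version, seed, config hash)
# in '#'-prefixed comment lines.

#' Run the full oximetry pipeline over a cohort
#'
#' Renders each animal/timepoint scene into a cube, extracts vessel
#' segments (threshold detection by default, or the ground-truth label
#' bypass), computes OD spectra, unmixes them into saturations and
#' averages multiple segments of the same arm per animal — the study's
#' per-animal analysis unit (`per_segment = TRUE` keeps segments
#' separate).
#'
#' @param cohort Tibble from [make_rvo_cohort()] (`animal`, `timepoint`,
#'   `scene`).
#' @param bands Cube band grid.
#' @param extinction Extinction table.
#' @param model An [oximetry_model()].
#' @param segmentation `"detect"` (threshold detection +
#'   [annotate_segments()]) or `"truth"` (label-image bypass).
#' @param per_segment Report one row per segment instead of averaging per
#'   animal arm.
#' @return Measurements tibble: `animal`, `timepoint`, `kind`, `region`,
#'   `so2_percent` (plus `segment_id`, `residual_norm` when
#'   `per_segment`).
#' @export
process_cohort <- function(cohort, bands = make_band_grid(),
                           extinction = hb_extinction(),
                           model = oximetry_model(),
                           segmentation = c("detect", "truth"),
                           per_segment = FALSE) {
  segmentation <- match.arg(segmentation)
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    cube <- render_cube(cohort$scene[[i]], bands, extinction)
    segs <- if (segmentation == "detect") {
      annotate_segments(detect_vessels(cube), cube)
    } else {
      segments_from_truth(cube)
    }
    if (!nrow(segs)) return(NULL)
    od <- compute_od(cube, segs)
    fits <- fit_so2(od, extinction, model)
    dplyr::mutate(
      dplyr::inner_join(
        tibble::as_tibble(fits),
        segs[, c("segment_id", "kind", "region")], by = "segment_id"),
      animal = cohort$animal[i], timepoint = cohort$timepoint[i])
  })
  rows <- dplyr::filter(rows, !.data$degenerate,
                        .data$kind != "unknown")
  if (per_segment) {
    return(dplyr::select(rows, "animal", "timepoint", "kind", "region",
                         "segment_id", "so2_percent", "residual_norm"))
  }
  dplyr::summarise(
    dplyr::group_by(rows, .data$animal, .data$timepoint, .data$kind,
                    .data$region),
    so2_percent = mean(.data$so2_percent), .groups = "drop")
}

provenance_header <- function(seed = NULL, config = NULL) {
  h <- c(sprintf("# retinox %s", as.character(packageVersion("retinox"))),
         sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed %d", seed))
  if (!is.null(config)) {
    h <- c(h, sprintf("# config_hash %s",
                      substr(rlang::hash(config), 1, 12)))
  }
  h
}

#' Write a tibble to CSV with a provenance comment header
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @param seed,config Recorded in `#` comment lines (config is hashed).
#' @return `path`, invisibly.
#' @export
write_provenance_csv <- function(data, path, seed = NULL, config = NULL) {
  writeLines(provenance_header(seed, config), path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_provenance_csv()]
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @return A tibble.
#' @export
read_provenance_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

cohort_spec_from_config <- function(cfg, seed = NULL) {
  if (!is.null(cfg$preset)) {
    spec <- rvo_cohort_preset(cfg$preset,
                              sampling = cfg$sampling %||% "normal",
                              seed = seed %||% cfg$seed %||% 1L,
                              n_animals = cfg$n_animals)
  } else {
    arms <- dplyr::bind_rows(lapply(cfg$arms, tibble::as_tibble))
    deltas <- if (is.null(cfg$deltas)) NULL else
      dplyr::bind_rows(lapply(cfg$deltas, tibble::as_tibble))
    spec <- cohort_spec(
      cfg$n_animals, arms,
      timepoints = unlist(cfg$timepoints) %||% c("baseline", "1h"),
      deltas = deltas,
      recannulation_timepoint = cfg$recannulation_timepoint,
      correlation = cfg$correlation %||% 0.7,
      sampling = cfg$sampling %||% "normal",
      seed = seed %||% cfg$seed %||% 1L)
  }
  spec
}

noise_from_config <- function(cfg) {
  if (is.null(cfg$noise)) return(noise_spec("none"))
  noise_spec(cfg$noise$kind %||% "gaussian",
             sigma = cfg$noise$sigma %||% 0.01,
             gain = cfg$noise$gain %||% 1)
}

#' Simulate a cohort to disk
#'
#' Renders every animal/timepoint cube of a cohort scenario and writes
#' them (ENVI dialect) together with the ground-truth CSV.
#'
#' @param config Path to a YAML scenario file, or an equivalent named
#'   list. Keys: `preset` or explicit `n_animals`/`arms`/`timepoints`/
#'   `deltas`/..., optional `noise` (`kind`, `sigma`), `sampling`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed.
#' @return Tibble listing the written cube paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  spec <- cohort_spec_from_config(cfg, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_rvo_cohort(spec, noise = noise_from_config(cfg))
  truth <- cohort_truth(spec)
  bands <- if (is.null(cfg$bands)) make_band_grid() else
    make_band_grid(cfg$bands$min %||% 450, cfg$bands$max %||% 700,
                   cfg$bands$n %||% 76)
  paths <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
    cube <- render_cube(cohort$scene[[i]], bands)
    p <- file.path(out_dir, sprintf("animal%02d_%s.raw",
                                    cohort$animal[i],
                                    cohort$timepoint[i]))
    write_cube(cube, p)
    p
  })
  write_provenance_csv(truth, file.path(out_dir, "truth.csv"),
                       seed = spec$seed, config = cfg)
  inform(sprintf("simulate: wrote %d cubes and truth.csv to %s",
                 length(paths), out_dir))
  invisible(dplyr::mutate(cohort[, c("animal", "timepoint")], path = paths))
}

#' Run oximetry over simulated cubes on disk
#'
#' Reads every cube written by [run_simulate()], runs detection, OD
#' extraction and unmixing, and writes per-animal measurements to
#' `measurements.csv` in `out_dir`.
#'
#' @param in_dir Directory of cubes from [run_simulate()].
#' @param out_dir Output directory.
#' @param model An [oximetry_model()].
#' @param segmentation `"detect"` or `"truth"`.
#' @return The measurements tibble, invisibly.
#' @export
run_oximetry <- function(in_dir, out_dir = in_dir,
                         model = oximetry_model(),
                         segmentation = c("detect", "truth")) {
  segmentation <- match.arg(segmentation)
  files <- sort(list.files(in_dir, pattern = "^animal.*\\.raw$",
                           full.names = TRUE))
  if (!length(files)) abort(sprintf("no cubes found in '%s'", in_dir))
  meas <- purrr::map_dfr(files, function(f) {
    cube <- read_cube(f)
    key <- regmatches(basename(f),
                      regexec("animal(\\d+)_(.*)\\.raw", basename(f)))[[1]]
    segs <- if (segmentation == "detect") {
      annotate_segments(detect_vessels(cube), cube)
    } else {
      segments_from_truth(cube)
    }
    if (!nrow(segs)) return(NULL)
    fits <- fit_so2(compute_od(cube, segs), model = model)
    df <- dplyr::inner_join(tibble::as_tibble(fits),
                            segs[, c("segment_id", "kind", "region")],
                            by = "segment_id")
    df <- dplyr::filter(df, !.data$degenerate, .data$kind != "unknown")
    dplyr::summarise(
      dplyr::group_by(df, .data$kind, .data$region),
      so2_percent = mean(.data$so2_percent), .groups = "drop") |>
      dplyr::mutate(animal = as.integer(key[2]), timepoint = key[3])
  })
  meas <- dplyr::select(meas, "animal", "timepoint", "kind", "region",
                        "so2_percent")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_provenance_csv(meas, file.path(out_dir, "measurements.csv"))
  inform(sprintf("oximetry: %d measurements written to %s",
                 nrow(meas), out_dir))
  invisible(meas)
}

#' Cohort statistics from a measurements CSV
#'
#' Writes the per-arm summary (`summary.csv`), the paired pre/post
#' t-tests (`ttests.csv`) and the arteriovenous differences (`av.csv`).
#'
#' @param measurements Path to a measurements CSV, or a measurements
#'   tibble.
#' @param out_dir Output directory.
#' @param baseline,post Timepoint labels compared by the paired tests.
#' @return Named list of the three tibbles, invisibly.
#' @export
run_study <- function(measurements, out_dir,
                      baseline = "baseline", post = "1h") {
  data <- if (is.character(measurements)) {
    read_provenance_csv(measurements)
  } else measurements
  if (is.null(data) || !nrow(data)) abort("no measurements")
  validate_measurements(data)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- summarize_arms(data)
  tests <- cohort_ttests(data, baseline, post)
  av <- av_difference(data)
  write_provenance_csv(summary, file.path(out_dir, "summary.csv"))
  write_provenance_csv(tests, file.path(out_dir, "ttests.csv"))
  write_provenance_csv(av, file.path(out_dir, "av.csv"))
  inform(sprintf("study: wrote summary.csv, ttests.csv, av.csv to %s",
                 out_dir))
  invisible(list(summary = summary, ttests = tests, av = av))
}

#' Render a pseudocolor oximetry map for a cube on disk
#'
#' @param cube_path Path to a cube written by [write_cube()].
#' @param out_png Output PNG path.
#' @param model An [oximetry_model()].
#' @param segmentation `"detect"` or `"truth"`.
#' @param per_pixel Fit each vessel pixel separately.
#' @return `out_png`, invisibly.
#' @export
run_render <- function(cube_path, out_png, model = oximetry_model(),
                       segmentation = c("detect", "truth"),
                       per_pixel = FALSE) {
  segmentation <- match.arg(segmentation)
  cube <- read_cube(cube_path)
  segs <- if (segmentation == "detect") detect_vessels(cube) else
    segments_from_truth(cube)
  map <- so2_map(cube, segs, model = model, per_pixel = per_pixel)
  render_pseudocolor(map, out_png)
  inform(sprintf("render: wrote %s", out_png))
  invisible(out_png)
}
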