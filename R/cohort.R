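# Paired pre/post cohort scenarios emulating the rabbit RVO study: an
# occlusion induced in the temporal vein, nasal vessels of the same eye as
# within-animal controls, optional laser-control arms (no occlusion, zero
# delta) and spontaneous recannulation restoring baseline saturations.

#' Describe a paired pre/post cohort scenario
#'
#' @param n_animals Number of animals (>= 1).
#' @param arms Tibble with columns `kind`, `region`, `mean_percent`,
#'   `sd_percent`: the per-arm baseline saturation assignment.
#' @param timepoints Character vector of timepoint labels; the first is
#'   baseline.
#' @param deltas Tibble with columns `timepoint`, `kind`, `region`,
#'   `delta_percent`: saturation change (percentage points) applied to the
#'   named arm at that timepoint. Arms without a row get delta 0.
#' @param recannulation_timepoint Optional timepoint label at which every
#'   vessel's saturation returns to that animal's baseline value.
#' @param correlation Within-animal correlation between baseline and
#'   follow-up draws (default 0.7; a paired design implies a positive
#'   correlation, and power simulations need it declared).
#' @param sampling `"normal"` draws each animal's saturation from
#'   normal(mean, sd); `"fixed"` assigns every animal the mean exactly.
#' @param seed Integer seed; same seed, same cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_animals, arms, timepoints = c("baseline", "1h"),
                        deltas = NULL, recannulation_timepoint = NULL,
                        correlation = 0.7,
                        sampling = c("normal", "fixed"), seed = 1L) {
  sampling <- match.arg(sampling)
  if (!is.finite(n_animals) || n_animals < 1) {
    abort("`n_animals` must be >= 1")
  }
  need <- c("kind", "region", "mean_percent", "sd_percent")
  if (!is.data.frame(arms) || !all(need %in% names(arms))) {
    abort(paste("`arms` must have columns", paste(need, collapse = ", ")))
  }
  if (length(timepoints) < 1L || anyDuplicated(timepoints)) {
    abort("`timepoints` must be distinct labels")
  }
  if (is.null(deltas)) {
    deltas <- tibble::tibble(timepoint = character(), kind = character(),
                             region = character(), delta_percent = numeric())
  }
  if (!is.null(recannulation_timepoint) &&
      !recannulation_timepoint %in% timepoints) {
    abort("`recannulation_timepoint` must be one of `timepoints`")
  }
  if (correlation < -1 || correlation > 1) {
    abort("`correlation` must lie in [-1, 1]")
  }
  structure(list(n_animals = as.integer(n_animals), arms = arms,
                 timepoints = timepoints, deltas = deltas,
                 recannulation_timepoint = recannulation_timepoint,
                 correlation = correlation, sampling = sampling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Preset cohort scenarios from the rabbit RVO study
#'
#' * `"rvo-baseline"`: n = 20, baseline temporal artery/vein 85.1/71.4%,
#'   nasal 85.2/69.2% (SDs 6.1/5.5/7.6/6.2), occlusion at 1 h dropping the
#'   temporal artery by 4.5 and the temporal vein by 7.4 points; nasal
#'   vessels unchanged (within-eye controls).
#' * `"laser-control-a"`: n = 5, laser adjacent to the vein, no occlusion:
#'   zero deltas (baseline 82.8/73.7%).
#' * `"laser-control-b"`: n = 5, sub-threshold laser on the vein, no
#'   occlusion: zero deltas (baseline 84.6/75.6%).
#' * `"recannulation"`: n = 3, occlusion deltas at 1 h and 1 wk, then
#'   spontaneous recannulation at 2 wk restoring baseline saturations.
#'
#' @param preset Scenario name.
#' @param sampling,seed,n_animals Overrides passed to [cohort_spec()];
#'   `n_animals = NULL` keeps the preset's count.
#' @return A [cohort_spec()].
#' @export
rvo_cohort_preset <- function(preset = c("rvo-baseline", "laser-control-a",
                                         "laser-control-b", "recannulation"),
                              sampling = "normal", seed = 1L,
                              n_animals = NULL) {
  preset <- match.arg(preset)
  arms_main <- tibble::tribble(
    ~kind,    ~region,    ~mean_percent, ~sd_percent,
    "artery", "temporal", 85.1,          6.1,
    "vein",   "temporal", 71.4,          5.5,
    "artery", "nasal",    85.2,          7.6,
    "vein",   "nasal",    69.2,          6.2
  )
  occl <- function(tp) tibble::tibble(
    timepoint = tp, kind = c("artery", "vein"),
    region = "temporal", delta_percent = c(-4.5, -7.4))
  spec <- switch(preset,
    "rvo-baseline" = cohort_spec(
      20, arms_main, c("baseline", "1h"), occl("1h"),
      sampling = sampling, seed = seed),
    "laser-control-a" = cohort_spec(
      5, dplyr::mutate(arms_main,
        mean_percent = c(82.8, 73.7, 85.2, 69.2),
        sd_percent = c(6.7, 4.4, 7.6, 6.2)),
      c("baseline", "1h"), NULL, sampling = sampling, seed = seed),
    "laser-control-b" = cohort_spec(
      5, dplyr::mutate(arms_main,
        mean_percent = c(84.6, 75.6, 85.2, 69.2),
        sd_percent = c(5.9, 6.3, 7.6, 6.2)),
      c("baseline", "1h"), NULL, sampling = sampling, seed = seed),
    "recannulation" = cohort_spec(
      3, arms_main, c("baseline", "1h", "1wk", "2wk"),
      dplyr::bind_rows(occl("1h"), occl("1wk")),
      recannulation_timepoint = "2wk",
      sampling = sampling, seed = seed)
  )
  if (!is.null(n_animals)) spec$n_animals <- as.integer(n_animals)
  spec
}

#' Ground-truth saturations for a cohort scenario
#'
#' Draws per-animal, per-arm saturations for every timepoint. Baseline
#' values come from the arm assignment (`normal` draw or fixed mean);
#' follow-up values target mean + delta with within-animal correlation
#' `rho`: `v_t = (mu + delta_t) + rho * (v_0 - mu) + sqrt(1 - rho^2) * sd *
#' eps`. At the recannulation timepoint every vessel returns to its own
#' baseline value. Deterministic given the spec's seed; values clipped to
#' \[0, 100\]%.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `animal`, `timepoint`, `kind`, `region`,
#'   `true_so2_percent`.
#' @export
cohort_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  arms <- spec$arms
  n <- spec$n_animals
  m <- nrow(arms)
  rho <- spec$correlation
  mu <- rep(arms$mean_percent, each = n)
  sig <- rep(arms$sd_percent, each = n)

  base <- if (spec$sampling == "fixed") mu else rnorm(n * m, mu, sig)
  arm_delta <- function(tp) {
    vapply(seq_len(m), function(j) {
      sel <- spec$deltas$timepoint == tp &
        spec$deltas$kind == arms$kind[j] &
        spec$deltas$region == arms$region[j]
      if (any(sel)) sum(spec$deltas$delta_percent[sel]) else 0
    }, numeric(1))
  }

  out <- purrr::map_dfr(seq_along(spec$timepoints), function(ti) {
    tp <- spec$timepoints[ti]
    recan <- !is.null(spec$recannulation_timepoint) &&
      tp == spec$recannulation_timepoint
    if (ti == 1L || recan) {
      vals <- base
    } else {
      delta <- rep(arm_delta(tp), each = n)
      vals <- if (spec$sampling == "fixed") mu + delta else
        (mu + delta) + rho * (base - mu) +
          sqrt(1 - rho^2) * sig * rnorm(n * m)
    }
    tibble::tibble(
      animal = rep(seq_len(n), times = m), timepoint = tp,
      kind = rep(arms$kind, each = n),
      region = rep(arms$region, each = n),
      true_so2_percent = pmin(100, pmax(0, vals)))
  })
  dplyr::arrange(out, .data$animal,
                 match(.data$timepoint, spec$timepoints))
}

#' Build the paired scene set for a cohort scenario
#'
#' Turns a cohort's ground truth into one renderable scene per animal and
#' timepoint (the medullary-ray preset of [rvo_scene()]), each scene
#' carrying its own derived noise seed.
#'
#' @param spec A [cohort_spec()].
#' @param noise A [noise_spec()] shared by all scenes.
#' @param ... Passed to [rvo_scene()] (geometry, scatter, illumination).
#' @return Tibble: `animal`, `timepoint`, and a `scene` list-column of
#'   [scene_spec()] objects.
#' @examples
#' coh <- make_rvo_cohort(rvo_cohort_preset("rvo-baseline",
#'                                          sampling = "fixed"))
#' nrow(coh)
#' @export
make_rvo_cohort <- function(spec, noise = noise_spec("none"), ...) {
  truth <- cohort_truth(spec)
  keys <- dplyr::distinct(truth, .data$animal, .data$timepoint)
  scenes <- purrr::map(seq_len(nrow(keys)), function(i) {
    tr <- dplyr::filter(truth, .data$animal == keys$animal[i],
                        .data$timepoint == keys$timepoint[i])
    so2 <- setNames(tr$true_so2_percent / 100,
                    paste(tr$region, tr$kind, sep = "_"))
    ti <- match(keys$timepoint[i], spec$timepoints)
    scene_seed <- (spec$seed %% 100000L) * 16384L +
      keys$animal[i] * 64L + ti
    rvo_scene(so2 = so2, noise = noise, seed = scene_seed, ...)
  })
  keys$scene <- scenes
  keys
}
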