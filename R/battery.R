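#' Build one scripted trial
#'
#' Solves the pedestrian path for a design, attaches the disappearance time
#' and the ground-truth label. Conditions with `dpc_m` in {-2, 0, +2} m are
#' collisions or near-collisions (closest distance under 1 m, so a collision
#' response is correct); `dpc_m = +12` m and parallel encounters are
#' noncollisions.
#'
#' @param design A design tibble from [encounter_design()] (any number of rows).
#' @return A trial tibble with path, `disappear_s` and `truth` columns.
#' @examples
#' build_trial(encounter_design("right", 10, 2))$truth # "collision"
#' @export
build_trial <- function(design) {
  design |>
    solve_pedestrian_path() |>
    dplyr::mutate(
      disappear_s = disappearance_time(design),
      truth = ifelse(is.finite(.data$dpc_m) & abs(.data$dpc_m) <= 2,
                     "collision", "noncollision")
    )
}

battery_composition <- function(dpc_convention) {
  crossing <- tidyr::expand_grid(
    side = c("left", "right"),
    beta0_deg = c(10, 30),
    dpc_m = c(-2, 0, 2, 12)
  )
  parallel <- tidyr::expand_grid(
    side = c("left", "right"),
    beta0_deg = c(2.5, 5),
    dpc_m = Inf
  )
  dplyr::bind_rows(crossing, parallel) |>
    dplyr::mutate(dpc_convention = dpc_convention)
}

#' Build a reproducible 20-trial scenario battery
#'
#' Each scenario contains 20 trials, 10 per side. Per side: two parallel
#' (sidewalk-like) noncollision encounters at 5 and 2.5 degree initial
#' bearings, four encounters at 10 degrees with path-crossing distances
#' -2, 0, +2 and +12 m, and four at 30 degrees with the same four distances.
#' Trial order is a seeded permutation; identical seeds give identical
#' batteries. A segment plan (see [build_segment_plan()]) is attached by
#' segment index.
#'
#' @param seed Integer seed controlling order and segment randomization.
#' @param dpc_convention Path-crossing convention, see [encounter_design()].
#' @param ... Passed to [encounter_design()] (e.g. `d0_m`, `t_cross_s`).
#' @return A 20-row trial tibble with `trial_id`, `segment_index` and design,
#'   path and truth columns.
#' @examples
#' b <- build_battery(seed = 1)
#' table(b$side)
#' @export
build_battery <- function(seed = 1L,
                          dpc_convention = c("crossing_ahead",
                                             "participant_at_crossing"),
                          ...) {
  dpc_convention <- match.arg(dpc_convention)
  comp <- battery_composition(dpc_convention)
  design <- encounter_design(
    side = comp$side, beta0_deg = comp$beta0_deg, dpc_m = comp$dpc_m,
    dpc_convention = dpc_convention, ...
  )
  trials <- build_trial(design)
  ord <- withr_seed(seed, sample.int(nrow(trials)))
  trials[ord, ] |>
    dplyr::mutate(
      trial_id = sprintf("T%02d", dplyr::row_number()),
      segment_index = dplyr::row_number(),
      battery_seed = as.integer(seed),
      .before = 1
    )
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build the walking-segment plan for a scenario
#'
#' A scenario is walked as 20 consecutive segments of about 45 m (23 s at
#' 1.94 m/s). At the start of each segment the guided path turns by a small
#' angle (uniform within +/- 5 degrees; only gradual turns keep programmed
#' and actual pedestrian bearings aligned) and the participant is allowed
#' 15 +/- 2 m (about 8 s) to realign before the segment's pedestrian appears.
#'
#' @param seed Integer seed.
#' @param n_segments Number of segments (default 20).
#' @param length_m Segment length in meters.
#' @param participant_speed_mps Walking speed (m/s).
#' @return A tibble with one row per segment: `segment_index`, `turn_deg`,
#'   `length_m`, `pre_appearance_m`, `traversal_s`.
#' @export
build_segment_plan <- function(seed = 1L, n_segments = 20L, length_m = 45,
                               participant_speed_mps = 1.94) {
  withr_seed(seed + 104729L, {
    tibble::tibble(
      segment_index = seq_len(n_segments),
      turn_deg = runif(n_segments, -5, 5),
      length_m = length_m,
      pre_appearance_m = runif(n_segments, 13, 17),
      traversal_s = length_m / participant_speed_mps
    )
  })
}
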