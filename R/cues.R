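#' Accumulated bearing deviation
#'
#' Sum of absolute deviations of the pedestrian's center bearing from its
#' initial (appearance) bearing, sampled every `dt_s` from appearance to
#' scripted disappearance. A pedestrian on a center-to-center collision
#' course keeps a constant bearing, so its accumulated deviation is zero;
#' larger miss distances produce larger drift.
#'
#' @param trial A one-row solved trial (with `disappear_s`).
#' @param dt_s Sampling interval (s).
#' @param form `"sum"` (default): plain sum over the samples, in degrees, as
#'   the cue is defined; `"integral"`: trapezoidal time integral of the
#'   deviation in degree-seconds, a sampling-stable alternative.
#' @return Accumulated deviation (degrees, or degree-seconds for the
#'   integral form).
#' @export
accumulated_bearing_deviation <- function(trial, dt_s = 0.1,
                                          form = c("sum", "integral")) {
  stopifnot(nrow(trial) == 1)
  form <- match.arg(form)
  if (dt_s <= 0) abort("`dt_s` must be positive.",
                       class = "prismwalk_invalid_argument")
  t <- seq(0, trial$disappear_s, by = dt_s)
  b <- relative_state(trial, t)$bearing_center_deg
  dev <- abs(b - b[1])
  # constant-bearing courses are constant analytically; suppress atan2
  # cancellation noise so they sum to an exact zero
  dev[dev < 1e-9] <- 0
  if (form == "sum") sum(dev) else sum((head(dev, -1) + dev[-1]) / 2) * dt_s
}

reference_collision <- function(trial) {
  encounter_design(
    side = trial$side, beta0_deg = trial$beta0_deg, dpc_m = 0,
    d0_m = trial$d0_m, t_cross_s = trial$t_cross_s,
    participant_speed_mps = trial$participant_speed_mps,
    body_diameter_m = trial$body_diameter_m,
    dpc_convention = trial$dpc_convention
  ) |>
    build_trial()
}

#' Bearing-span overlap with the matched center-to-center collision
#'
#' At each sample the bearing span (the angular interval subtended by the
#' cylindrical body, clipped to +/-90 degrees) of the trial is intersected
#' with the span of the reference center-to-center colliding pedestrian that
#' starts at the same initial bearing, side and distance. The summed
#' intersection over the common lifetime (the shorter of the two scripted
#' walks), divided by the reference's summed span, gives the percent overlap.
#'
#' @param trial A one-row solved trial.
#' @param reference Optional one-row solved reference trial; defaults to the
#'   matched center-to-center collision.
#' @param dt_s Sampling interval (s).
#' @return Overlap percentage in [0, 100]; `NA` with a warning if the
#'   reference span area is zero.
#' @export
bearing_span_overlap_pct <- function(trial, reference = NULL, dt_s = 0.1) {
  stopifnot(nrow(trial) == 1)
  if (is.null(reference)) reference <- reference_collision(trial)
  t_end <- min(trial$disappear_s, reference$disappear_s)
  t <- seq(0, t_end, by = dt_s)
  span <- function(tr) {
    st <- relative_state(tr, t)
    lo <- pmax(-90, st$bearing_center_deg - st$half_span_deg)
    hi <- pmin(90, st$bearing_center_deg + st$half_span_deg)
    list(lo = lo, hi = hi)
  }
  a <- span(trial)
  b <- span(reference)
  inter <- pmax(0, pmin(a$hi, b$hi) - pmax(a$lo, b$lo))
  ref_area <- sum(b$hi - b$lo)
  if (ref_area == 0) {
    warn("Reference bearing-span area is zero; overlap undefined.")
    return(NA_real_)
  }
  100 * sum(inter) / ref_area
}

#' Per-trial collision cues
#'
#' Computes, for every trial of a battery, the three collision cues: the
#' accumulated bearing deviation, the bearing-span overlap with the matched
#' center-to-center collision, and the closest center-to-center distance
#' (with paths extrapolated past disappearance).
#'
#' @param battery A solved trial tibble from [build_battery()].
#' @param dt_s Sampling interval for the sampled cues (s).
#' @return A tibble with one row per trial: `trial_id`, design identifiers,
#'   `abd_deg`, `abd_degs` (time-integral form, degree-seconds),
#'   `overlap_pct`, `dmin_m`, `tmin_s`.
#' @examples
#' compute_cues(build_battery(1))
#' @export
compute_cues <- function(battery, dt_s = 0.1) {
  ca <- closest_approach(battery)
  rows <- purrr::map(seq_len(nrow(battery)), function(i) {
    tr <- battery[i, ]
    abd <- accumulated_bearing_deviation(tr, dt_s)
    tibble::tibble(
      abd_deg = abd,
      abd_degs = accumulated_bearing_deviation(tr, dt_s, form = "integral"),
      overlap_pct = bearing_span_overlap_pct(tr, dt_s = dt_s)
    )
  })
  dplyr::bind_cols(
    battery |>
      dplyr::select(dplyr::any_of(c("trial_id", "side", "beta0_deg", "dpc_m"))),
    dplyr::bind_rows(rows),
    ca |> dplyr::select(dmin_m = "dmin_m", tmin_s = "t_star_s")
  )
}
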