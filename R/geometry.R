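#' Convert prism power to deviation angle
#'
#' Prism power in prism diopters deviates a ray 1 cm per diopter at 1 m, so
#' the deviation angle is `atan(power / 100)`. A 57 prism-diopter prism
#' deviates light by about 30 degrees.
#'
#' @param power_pd Prism power in prism diopters (non-negative).
#' @return Deviation angle in degrees.
#' @examples
#' deg_from_prism_diopters(57) # ~29.68
#' @export
deg_from_prism_diopters <- function(power_pd) {
  if (any(power_pd < 0)) {
    abort("`power_pd` must be non-negative.", class = "prismwalk_invalid_argument")
  }
  rad2deg(atan(power_pd / 100))
}

#' Specify a pedestrian encounter
#'
#' Builds the design table for one or more scripted encounters between a
#' forward-walking participant and an approaching pedestrian. The participant
#' starts at the origin heading along +y at constant speed; the pedestrian
#' appears at distance `d0_m` and unsigned bearing `beta0_deg` on the given
#' side (right of heading = positive x). For finite path-crossing distances
#' the pedestrian reaches the participant's path line at `t_cross_s`;
#' `dpc_m = Inf` marks the sidewalk-like encounter on exactly antiparallel
#' paths with lateral offset `parallel_offset_m` (for which `d0_m` is derived
#' from the offset and initial bearing).
#'
#' Two conventions for realising a finite signed `dpc_m` are supported:
#' \describe{
#'   \item{`"crossing_ahead"` (default)}{the crossing point on the
#'     participant's path line lies `dpc_m` ahead of the participant's
#'     position at `t_cross_s`, and the pedestrian reaches it at `t_cross_s`.}
#'   \item{`"participant_at_crossing"`}{the participant is at the crossing
#'     point at `t_cross_s`, and at that moment the pedestrian is `dpc_m`
#'     past the crossing point along its own path (positive = has already
#'     crossed, passing in front).}
#' }
#'
#' @param side `"left"` or `"right"`.
#' @param beta0_deg Initial pedestrian bearing magnitude in degrees,
#'   strictly between 0 and 90.
#' @param dpc_m Signed path-crossing distance in meters, or `Inf` for
#'   antiparallel (sidewalk-like) encounters.
#' @param d0_m Initial center-to-center distance (m). Ignored (derived) for
#'   parallel encounters.
#' @param t_cross_s Time at which the pedestrian reaches the participant's
#'   path line (s); abeam-passage time for parallel encounters.
#' @param participant_speed_mps Participant walking speed (m/s).
#' @param body_diameter_m Pedestrian body diameter (m), modeled as a cylinder.
#' @param parallel_offset_m Lateral path separation for parallel encounters (m).
#' @param dpc_convention Convention for finite `dpc_m`; see Details.
#' @return A tibble with one row per encounter.
#' @examples
#' encounter_design("right", 30, 0)
#' encounter_design("left", 5, Inf)
#' @export
encounter_design <- function(side, beta0_deg, dpc_m,
                             d0_m = 19.4, t_cross_s = 6,
                             participant_speed_mps = 1.94,
                             body_diameter_m = 0.6,
                             parallel_offset_m = 1.69,
                             dpc_convention = c("crossing_ahead",
                                                "participant_at_crossing")) {
  dpc_convention <- match.arg(dpc_convention)
  d <- tibble::tibble(
    side = as.character(side),
    beta0_deg = as.numeric(beta0_deg),
    dpc_m = as.numeric(dpc_m),
    d0_m = as.numeric(d0_m),
    t_cross_s = as.numeric(t_cross_s),
    participant_speed_mps = as.numeric(participant_speed_mps),
    body_diameter_m = as.numeric(body_diameter_m),
    parallel_offset_m = as.numeric(parallel_offset_m),
    dpc_convention = dpc_convention
  )
  validate_design(d)
  d
}

validate_design <- function(d) {
  bad <- function(msg) abort(msg, class = "prismwalk_invalid_design")
  if (!all(d$side %in% c("left", "right"))) bad("`side` must be 'left' or 'right'.")
  if (!all(d$beta0_deg > 0 & d$beta0_deg < 90)) {
    bad("`beta0_deg` must lie strictly between 0 and 90 degrees.")
  }
  if (!all(d$d0_m > 0)) bad("`d0_m` must be positive.")
  if (!all(d$t_cross_s > 0)) bad("`t_cross_s` must be positive.")
  if (!all(d$participant_speed_mps > 0)) bad("`participant_speed_mps` must be positive.")
  if (!all(d$body_diameter_m > 0)) bad("`body_diameter_m` must be positive.")
  par <- is.infinite(d$dpc_m)
  if (any(par) && !all(d$parallel_offset_m[par] > 0)) {
    bad("`parallel_offset_m` must be positive for parallel encounters.")
  }
  invisible(d)
}

#' Solve the pedestrian path for an encounter design
#'
#' Computes the pedestrian's constant-velocity start position, heading and
#' speed satisfying the design constraints: initial bearing and distance at
#' appearance, and the path-crossing geometry at `t_cross_s`. Headings are in
#' degrees clockwise from the participant's heading (+y), normalized to
#' (-180, 180].
#'
#' @param design A design tibble from [encounter_design()].
#' @return The design with columns `start_x_m`, `start_y_m`, `heading_deg`,
#'   `speed_mps` appended (and `d0_m` replaced by the derived value for
#'   parallel encounters).
#' @examples
#' solve_pedestrian_path(encounter_design("right", 30, 0))$speed_mps # ~1.831
#' @export
solve_pedestrian_path <- function(design) {
  validate_design(design)
  sgn <- ifelse(design$side == "right", 1, -1)
  par <- is.infinite(design$dpc_m)
  vP <- design$participant_speed_mps
  tc <- design$t_cross_s

  d0 <- design$d0_m
  d0[par] <- design$parallel_offset_m[par] / sin(deg2rad(design$beta0_deg[par]))

  sx <- sgn * d0 * sin(deg2rad(design$beta0_deg))
  sy <- d0 * cos(deg2rad(design$beta0_deg))

  vx <- vy <- numeric(nrow(design))

  # antiparallel: pedestrian walks straight toward -y, abeam at t_cross
  vy[par] <- -(sy[par] - vP[par] * tc[par]) / tc[par]
  vx[par] <- 0
  if (any(par & vy > 0)) {
    abort("Infeasible parallel design: pedestrian would need negative speed.",
          class = "prismwalk_infeasible_design")
  }

  fin <- !par
  ahead <- fin & design$dpc_convention == "crossing_ahead"
  if (any(ahead)) {
    tx <- 0
    ty <- vP[ahead] * tc[ahead] + design$dpc_m[ahead]
    vx[ahead] <- (tx - sx[ahead]) / tc[ahead]
    vy[ahead] <- (ty - sy[ahead]) / tc[ahead]
  }
  pac <- fin & design$dpc_convention == "participant_at_crossing"
  if (any(pac)) {
    cx <- 0
    cy <- vP[pac] * tc[pac]
    dx <- cx - sx[pac]
    dy <- cy - sy[pac]
    len <- sqrt(dx^2 + dy^2)
    tot <- len + design$dpc_m[pac] # path length covered by t_cross
    if (any(tot <= 0)) {
      abort("Infeasible design: pedestrian path length by t_cross is not positive.",
            class = "prismwalk_infeasible_design")
    }
    vx[pac] <- dx / len * tot / tc[pac]
    vy[pac] <- dy / len * tot / tc[pac]
  }

  design |>
    dplyr::mutate(
      d0_m = d0,
      start_x_m = sx,
      start_y_m = sy,
      heading_deg = norm_deg(rad2deg(atan2(vx, vy))),
      speed_mps = sqrt(vx^2 + vy^2)
    )
}

ped_velocity <- function(trial) {
  list(vx = trial$speed_mps * sin(deg2rad(trial$heading_deg)),
       vy = trial$speed_mps * cos(deg2rad(trial$heading_deg)))
}

#' Relative bearing state of the pedestrian
#'
#' For a solved trial, returns the pedestrian's signed center bearing
#' (right of heading positive), angular half-span of the cylindrical body,
#' and center-to-center distance at the requested times. The half span is
#' `asin(min(1, body_radius / distance))`; at zero distance the bearing is
#' undefined and flagged.
#'
#' @param trial A one-row solved trial (from [solve_pedestrian_path()] or a
#'   battery row).
#' @param t Numeric vector of times since pedestrian appearance (s, >= 0).
#' @param body_radius_m Body radius (m); defaults to half the design diameter.
#' @return A tibble with `t_s`, `bearing_center_deg`, `half_span_deg`,
#'   `distance_m`, `ecc_near_deg` (eccentricity of the nearest body edge,
#'   floored at 0) and `bearing_undefined`.
#' @export
relative_state <- function(trial, t, body_radius_m = trial$body_diameter_m / 2) {
  stopifnot(nrow(trial) == 1)
  if (any(t < 0)) abort("`t` must be non-negative.", class = "prismwalk_invalid_argument")
  v <- ped_velocity(trial)
  rx <- trial$start_x_m + v$vx * t
  ry <- trial$start_y_m + (v$vy - trial$participant_speed_mps) * t
  dist <- sqrt(rx^2 + ry^2)
  undef <- dist == 0
  bearing <- ifelse(undef, NA_real_, rad2deg(atan2(rx, ry)))
  ratio <- ifelse(dist > 0, pmin(1, body_radius_m / dist), 1)
  half <- rad2deg(asin(ratio))
  tibble::tibble(
    t_s = t,
    bearing_center_deg = bearing,
    half_span_deg = half,
    distance_m = dist,
    ecc_near_deg = pmax(0, abs(bearing) - half),
    bearing_undefined = undef
  )
}

#' Closest approach between participant and pedestrian
#'
#' Closed-form minimization of the center-to-center separation of the two
#' constant-velocity agents over `t >= 0`, with paths extrapolated
#' indefinitely (collision judgments assume the pedestrian continues on the
#' same path past its scripted disappearance). If separation is increasing
#' from the start, the minimum is at `t = 0`.
#'
#' @param trials A solved trial tibble (any number of rows).
#' @return The input with `t_star_s` and `dmin_m` appended.
#' @examples
#' encounter_design("left", 5, Inf) |>
#'   solve_pedestrian_path() |>
#'   closest_approach() # dmin_m = 1.69
#' @export
closest_approach <- function(trials) {
  v <- ped_velocity(trials)
  vrx <- v$vx
  vry <- v$vy - trials$participant_speed_mps
  rx <- trials$start_x_m
  ry <- trials$start_y_m
  v2 <- vrx^2 + vry^2
  ts <- ifelse(v2 == 0, 0, pmax(0, -(rx * vrx + ry * vry) / v2))
  dmin <- sqrt((rx + vrx * ts)^2 + (ry + vry * ts)^2)
  trials |>
    dplyr::mutate(t_star_s = ts, dmin_m = dmin)
}

#' Time at which the pedestrian enters a central field
#'
#' Earliest time at which the near edge of the pedestrian's bearing span
#' (center bearing magnitude minus half span) falls within the given field
#' half-angle, searched from appearance up to the time of closest approach.
#' Returns `NA` if the pedestrian never enters before closest approach.
#'
#' @param trial A one-row solved trial.
#' @param field_half_angle_deg Field half-angle in degrees (0, 90).
#' @param body_radius_m Body radius (m).
#' @return Entry time in seconds, or `NA_real_`.
#' @export
field_entry_time <- function(trial, field_half_angle_deg = 10,
                             body_radius_m = trial$body_diameter_m / 2) {
  stopifnot(nrow(trial) == 1)
  if (field_half_angle_deg <= 0 || field_half_angle_deg >= 90) {
    abort("`field_half_angle_deg` must lie in (0, 90).",
          class = "prismwalk_invalid_argument")
  }
  tmax <- closest_approach(trial)$t_star_s
  g <- function(t) {
    relative_state(trial, t, body_radius_m)$ecc_near_deg - field_half_angle_deg
  }
  if (g(0) <= 0) return(0)
  if (tmax <= 0) return(NA_real_)
  grid <- seq(0, tmax, length.out = max(64L, ceiling(tmax / 0.005)))
  vals <- g(grid)
  idx <- which(vals <= 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  uniroot(g, c(grid[i - 1], grid[i]), tol = 1e-9)$root
}

#' Scripted disappearance time of the pedestrian
#'
#' Pedestrians on path-crossing courses disappear 0.1 s before reaching the
#' participant's path line, to avoid rendering an actual collision or bypass;
#' pedestrians on parallel paths persist until abeam passage.
#'
#' @param design A design tibble.
#' @return Disappearance times (s), one per row.
#' @export
disappearance_time <- function(design) {
  ifelse(is.infinite(design$dpc_m), design$t_cross_s,
         pmax(0, design$t_cross_s - 0.1))
}
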