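#' Goggle and prism specifications
#'
#' `goggle_spec()` describes the opaque goggles simulating peripheral field
#' loss: a circular open aperture giving a binocular residual central field
#' of `field_diameter_deg` at back vertex distance `vertex_mm`.
#' `prism_spec()` describes the oblique high-power Fresnel prisms placed over
#' the upper and lower portions of the aperture (beyond the prism-free
#' central vertical clear zone), base-out, with the apex-base axis tilted
#' from horizontal so that the laterally expanded field is shifted to eye
#' level.
#'
#' @param field_diameter_deg Residual central field diameter (degrees).
#' @param vertex_mm Back vertex distance from cornea to aperture plane (mm).
#' @return A list of class `prismwalk_goggles` / `prismwalk_prism`.
#' @examples
#' goggle_spec()
#' prism_spec()
#' @export
goggle_spec <- function(field_diameter_deg = 20, vertex_mm = 100) {
  if (field_diameter_deg < 0 || field_diameter_deg >= 180) {
    abort("`field_diameter_deg` must lie in [0, 180).",
          class = "prismwalk_invalid_argument")
  }
  if (vertex_mm <= 0) abort("`vertex_mm` must be positive.",
                            class = "prismwalk_invalid_argument")
  structure(list(field_diameter_deg = field_diameter_deg,
                 vertex_mm = vertex_mm),
            class = "prismwalk_goggles")
}

#' @rdname goggle_spec
#' @param power_pd Prism power (prism diopters).
#' @param tilt_deg Tilt of the apex-base axis from horizontal (degrees).
#' @param clear_half_height_deg Half-height of the prism-free central clear
#'   zone (degrees).
#' @param refractive_index Prism material index (press-on Fresnel ~1.5).
#' @param vertical_center_shift_deg Vertical shift bringing the expanded
#'   field center to eye level (degrees).
#' @param eye_rotation_center_mm Distance from cornea to the eye's center of
#'   rotation (mm); incidence angles are computed from the rotation center.
#' @export
prism_spec <- function(power_pd = 57, tilt_deg = 17,
                       clear_half_height_deg = 5,
                       refractive_index = 1.5,
                       vertical_center_shift_deg = 7.5,
                       eye_rotation_center_mm = 13.5) {
  if (power_pd <= 0) abort("`power_pd` must be positive.",
                           class = "prismwalk_invalid_argument")
  if (tilt_deg < 0 || tilt_deg >= 90) {
    abort("`tilt_deg` must lie in [0, 90).", class = "prismwalk_invalid_argument")
  }
  structure(list(power_pd = power_pd, tilt_deg = tilt_deg,
                 clear_half_height_deg = clear_half_height_deg,
                 refractive_index = refractive_index,
                 vertical_center_shift_deg = vertical_center_shift_deg,
                 eye_rotation_center_mm = eye_rotation_center_mm),
            class = "prismwalk_prism")
}

#' Aperture radius on the goggle plane
#'
#' Radius of the circular opening that subtends the residual central field
#' at the back vertex distance: `vertex_mm * tan(field_diameter / 2)`.
#'
#' @param goggles A [goggle_spec()].
#' @return Radius in mm.
#' @examples
#' aperture_radius_mm(goggle_spec(20, 100)) # 17.63
#' @export
aperture_radius_mm <- function(goggles) {
  goggles$vertex_mm * tan(deg2rad(goggles$field_diameter_deg / 2))
}

#' Widest horizontal field of view within the prism
#'
#' The prisms cover the aperture beyond the central clear zone, so the widest
#' horizontal angular chord available through a prism lies at the prism's
#' inner edge: `2 * atan(sqrt(tan(r)^2 - tan(h)^2))` with field radius `r`
#' and clear half-height `h`.
#'
#' @param goggles A [goggle_spec()].
#' @param prism A [prism_spec()].
#' @return Width in degrees.
#' @examples
#' widest_prism_span_deg(goggle_spec(), prism_spec()) # 17.4
#' @export
widest_prism_span_deg <- function(goggles, prism) {
  r <- goggles$field_diameter_deg / 2
  h <- prism$clear_half_height_deg
  if (h > r) abort("Clear zone covers the whole aperture: no prism region.",
                   class = "prismwalk_empty_prism")
  2 * rad2deg(atan(sqrt(tan(deg2rad(r))^2 - tan(deg2rad(h))^2)))
}

#' Apex angle reproducing a nominal prism power
#'
#' Finds the wedge apex angle whose exact two-surface ray-traced deviation at
#' normal incidence equals the nominal deviation `atan(power / 100)`. High
#' powers have no solution below the total-internal-reflection limit.
#'
#' @param power_pd Prism power (prism diopters).
#' @param n Refractive index.
#' @return Apex angle in degrees.
#' @examples
#' solve_apex_angle(57) # ~38.11
#' @export
solve_apex_angle <- function(power_pd, n = 1.5) {
  target <- deg_from_prism_diopters(power_pd)
  amax <- rad2deg(asin(1 / n)) - 1e-9
  f <- function(a) trace_prism_deviation(0, a, n)$deviation_deg - target
  if (f(amax) < 0 || !is.finite(f(amax))) {
    abort("No apex angle below the TIR limit yields this power.",
          class = "prismwalk_infeasible_prism")
  }
  uniroot(f, c(1e-9, amax), tol = 1e-10)$root
}

#' Exact two-surface prism deviation
#'
#' Snell-law ray trace through a thin wedge with the flat (Fresnel) face
#' toward the eye and the base toward positive incidence. `incidence_deg` is
#' the ray angle at the eye-side flat face, positive toward the base. The
#' internal angle at the exit face is `apex + asin(sin(incidence)/n)`; rays
#' whose internal exit angle exceeds the critical angle are totally
#' internally reflected.
#'
#' @param incidence_deg Incidence angles at the eye-side face (degrees,
#'   |incidence| < 90). Vectorized.
#' @param apex_deg Wedge apex angle (degrees).
#' @param n Refractive index.
#' @return A tibble with `incidence_deg`, `deviation_deg` (`NA` under TIR),
#'   `tir` flag, and `transmittance` (product of unpolarized Fresnel
#'   transmittances at both surfaces; 0 under TIR).
#' @examples
#' trace_prism_deviation(0, solve_apex_angle(57), 1.5)$deviation_deg # 29.68
#' @export
trace_prism_deviation <- function(incidence_deg, apex_deg, n = 1.5) {
  if (any(abs(incidence_deg) >= 90)) {
    abort("`incidence_deg` must satisfy |incidence| < 90.",
          class = "prismwalk_invalid_argument")
  }
  th1 <- deg2rad(incidence_deg)
  A <- deg2rad(apex_deg)
  r1 <- asin(sin(th1) / n)
  inc2 <- A + r1
  s <- n * sin(inc2)
  tir <- abs(s) >= 1
  th2 <- ifelse(tir, NA_real_, asin(pmin(1, pmax(-1, s))))
  dev <- rad2deg(th2 - A) - incidence_deg
  trans <- ifelse(tir, 0,
                  fresnel_T(th1, r1, 1, n) * fresnel_T(inc2, th2, n, 1))
  tibble::tibble(incidence_deg = incidence_deg,
                 deviation_deg = dev,
                 tir = tir,
                 transmittance = trans)
}

# unpolarized Fresnel power transmittance across one interface
fresnel_T <- function(ti, tt, n1, n2) {
  Rs <- ((n1 * cos(ti) - n2 * cos(tt)) / (n1 * cos(ti) + n2 * cos(tt)))^2
  Rp <- ((n1 * cos(tt) - n2 * cos(ti)) / (n1 * cos(tt) + n2 * cos(ti)))^2
  1 - (Rs + Rp) / 2
}

#' Horizontal and vertical components of an oblique deviation
#'
#' Small-angle vector decomposition of a prism deviation along an apex-base
#' axis tilted from horizontal: `horizontal = deviation * cos(tilt)`,
#' `vertical = deviation * sin(tilt)`. An approximation that is accurate to
#' well under a degree for the tilts used here; the exact 3-D split is not
#' modeled.
#'
#' @param deviation_deg Deviation magnitude (degrees).
#' @param tilt_deg Axis tilt from horizontal (degrees).
#' @return A tibble with `horizontal_deg`, `vertical_deg`.
#' @examples
#' oblique_components(26, 17) # vertical ~7.6
#' @export
oblique_components <- function(deviation_deg, tilt_deg) {
  tibble::tibble(
    horizontal_deg = deviation_deg * cos(deg2rad(tilt_deg)),
    vertical_deg = deviation_deg * sin(deg2rad(tilt_deg))
  )
}

#' Lateral island of scene eccentricities visible through a prism
#'
#' Traces eye-side directions across the widest in-prism horizontal chord
#' through the exact two-surface deviation, takes the horizontal component of
#' the oblique deviation, excludes totally internally reflected rays, and
#' maps exit rays onto the display surface at `scene_distance_mm` (the
#' apparatus renders scenes and perimetry targets on screens at finite
#' distance, so exit-ray parallax from the aperture plane compresses apparent
#' eccentricities; use `Inf` for far-field scenes). Because transmission
#' falls continuously to zero at grazing exit near the TIR limit, the island
#' has no hard outer geometric edge; the reported outer bound is the
#' half-maximum point where transmittance drops below half its
#' normal-incidence value. Eccentricities are unsigned (per side); mirror for
#' the left/right island.
#'
#' @param goggles A [goggle_spec()].
#' @param prism A [prism_spec()].
#' @param scene_distance_mm Distance from the eye to the displayed scene (mm).
#' @return A tibble with `inner_deg`, `outer_deg`, `tir_from_deg` (apparent
#'   eccentricity at which the TIR-dimmed band begins, `NA` if no TIR within
#'   the chord).
#' @examples
#' island_extent(goggle_spec(), prism_spec()) # ~[11.2, 40.6]
#' @export
island_extent <- function(goggles, prism, scene_distance_mm = 735) {
  half_chord <- widest_prism_span_deg(goggles, prism) / 2
  if (prism$power_pd == 0) {
    return(tibble::tibble(inner_deg = 0, outer_deg = half_chord,
                          tir_from_deg = NA_real_))
  }
  apex <- solve_apex_angle(prism$power_pd, prism$refractive_index)
  phi <- seq(-half_chord, half_chord, by = 0.001)
  tr <- trace_prism_deviation(phi, apex, prism$refractive_index)
  dev_h <- tr$deviation_deg * cos(deg2rad(prism$tilt_deg))
  exit_dir <- phi + dev_h
  ecc <- apparent_eccentricity(phi, exit_dir, goggles, prism, scene_distance_mm)
  t0 <- trace_prism_deviation(0, apex, prism$refractive_index)$transmittance
  vis <- !tr$tir & tr$transmittance >= t0 / 2
  if (!any(vis)) {
    abort("No transmitted rays through the prism region.",
          class = "prismwalk_infeasible_prism")
  }
  truncated <- any(tr$tir) || any(!tr$tir & tr$transmittance < t0 / 2)
  tibble::tibble(
    inner_deg = min(ecc[vis]),
    outer_deg = max(ecc[vis]),
    tir_from_deg = if (truncated) max(ecc[vis]) else NA_real_
  )
}

# map an eye-side aperture direction and exit-ray direction to the apparent
# angular position of the intersected scene point on a display at finite
# distance; collapses to the exit direction for far scenes
apparent_eccentricity <- function(phi_deg, exit_dir_deg, goggles, prism,
                                  scene_distance_mm) {
  if (is.infinite(scene_distance_mm)) return(exit_dir_deg)
  z0 <- goggles$vertex_mm + prism$eye_rotation_center_mm
  zs <- scene_distance_mm + prism$eye_rotation_center_mm
  x <- z0 * tan(deg2rad(phi_deg)) + (zs - z0) * tan(deg2rad(exit_dir_deg))
  rad2deg(atan(x / zs))
}

#' Assemble a visual-field model
#'
#' Combines the residual central field with the optional per-side
#' prism-expanded lateral islands into the bearing intervals visible to the
#' observer. Bearings are signed (right positive). The vertical structure is
#' collapsed: pedestrians are treated as at eye level within the islands
#' (the prisms' vertical shift centers the expanded fields at eye level),
#' and visibility is decided on horizontal bearing intervals alone. Eye of
#' origin and apparent (upper/lower) position of each island are carried as
#' metadata only.
#'
#' @param goggles A [goggle_spec()], or `NULL` for unrestricted normal vision.
#' @param prism A [prism_spec()], or `NULL` for goggles without prisms.
#' @param scene_distance_mm Display distance for the island trace (mm).
#' @return A list of class `prismwalk_field` with elements
#'   `central_half_angle_deg` and `islands` (tibble with one row per side).
#' @examples
#' field_model(goggle_spec(), prism_spec())
#' @export
field_model <- function(goggles = goggle_spec(), prism = NULL,
                        scene_distance_mm = 735) {
  if (is.null(goggles)) {
    return(structure(list(central_half_angle_deg = 90,
                          islands = empty_islands()),
                     class = "prismwalk_field"))
  }
  islands <- empty_islands()
  if (!is.null(prism)) {
    ext <- island_extent(goggles, prism, scene_distance_mm)
    islands <- tibble::tibble(
      side = c("left", "right"),
      lo_deg = c(-ext$outer_deg, ext$inner_deg),
      hi_deg = c(-ext$inner_deg, ext$outer_deg),
      eye = c("left", "right"),
      apparent_position = c("upper", "lower")
    )
  }
  structure(list(central_half_angle_deg = goggles$field_diameter_deg / 2,
                 islands = islands),
            class = "prismwalk_field")
}

empty_islands <- function() {
  tibble::tibble(side = character(), lo_deg = numeric(), hi_deg = numeric(),
                 eye = character(), apparent_position = character())
}

#' Classify where in the field the pedestrian is visible
#'
#' For a trial and field model, decides for each time whether the near edge
#' of the pedestrian's bearing span lies in the residual central field
#' (`"central"`), in a prism-expanded island (`"island"`), or is invisible
#' (`"none"`). Ties at the central boundary resolve to central.
#'
#' @param trial A one-row solved trial.
#' @param field A `prismwalk_field` from [field_model()].
#' @param t Times since appearance (s), within `[0, disappear_s]`.
#' @return Character vector of regions, one per time.
#' @export
classify_visibility <- function(trial, field, t) {
  st <- relative_state(trial, t)
  region <- rep("none", length(t))
  region[st$ecc_near_deg <= field$central_half_angle_deg] <- "central"
  if (nrow(field$islands) > 0) {
    # nearest body edge bearing, signed
    near_signed <- sign(st$bearing_center_deg) * st$ecc_near_deg
    for (i in seq_len(nrow(field$islands))) {
      isl <- field$islands[i, ]
      inside <- region == "none" &
        near_signed >= isl$lo_deg & near_signed <= isl$hi_deg
      region[inside] <- "island"
    }
  }
  region
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Perimetry-style field map
#'
#' Renders the modeled visual field as filled bearing sectors: the central
#' disc plus the lateral islands.
#'
#' @param object A `prismwalk_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prismwalk_field <- function(object, ...) {
  field <- object
  bands <- tibble::tibble(
    lo = -field$central_half_angle_deg,
    hi = field$central_half_angle_deg,
    region = "central"
  )
  if (nrow(field$islands) > 0) {
    bands <- dplyr::bind_rows(
      bands,
      tibble::tibble(lo = field$islands$lo_deg, hi = field$islands$hi_deg,
                     region = "island")
    )
  }
  ggplot2::ggplot(bands) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = -1, ymax = 1,
                                    fill = .data$region)) +
    ggplot2::scale_x_continuous("bearing (deg, right positive)",
                                limits = c(-90, 90)) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(fill = NULL, title = "Modeled visual field") +
    ggplot2::theme_minimal()
}
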