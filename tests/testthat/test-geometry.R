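test_that("prism-diopter conversion follows arctan(power/100)", {
  expect_equal(deg_from_prism_diopters(57), 29.68, tolerance = 1e-3)
  expect_equal(deg_from_prism_diopters(0), 0)
  expect_equal(deg_from_prism_diopters(100), 45)
  expect_error(deg_from_prism_diopters(-1), class = "prismwalk_invalid_argument")
})

test_that("solved pedestrian speeds match the designed crossing geometry", {
  expect_equal(solve_pedestrian_path(encounter_design("right", 30, 0))$speed_mps,
               1.831, tolerance = 1e-3)
  expect_equal(solve_pedestrian_path(encounter_design("right", 10, 0))$speed_mps,
               1.365, tolerance = 1e-3)
  par <- solve_pedestrian_path(encounter_design("left", 5, Inf))
  expect_equal(par$speed_mps, 1.281, tolerance = 3e-3)
  expect_equal(abs(par$heading_deg), 180)
  # lateral offset is the authoritative parallel constraint; d0 is derived
  expect_equal(par$d0_m, 1.69 / sin(5 * pi / 180))
})

test_that("design validation rejects out-of-range parameters", {
  expect_error(encounter_design("right", 95, 0), class = "prismwalk_invalid_design")
  expect_error(encounter_design("right", 30, 0, d0_m = -1),
               class = "prismwalk_invalid_design")
  expect_error(encounter_design("up", 30, 0), class = "prismwalk_invalid_design")
})

test_that("relative state reproduces bearings, spans and degenerate cases", {
  for (b0 in c(10, 30)) {
    tr <- solve_pedestrian_path(encounter_design("right", b0, 2))
    expect_equal(relative_state(tr, 0)$bearing_center_deg, b0, tolerance = 1e-9)
  }
  trL <- solve_pedestrian_path(encounter_design("left", 30, 0))
  expect_equal(relative_state(trL, 0)$bearing_center_deg, -30, tolerance = 1e-9)
  # half span: arcsin(radius / distance)
  tr <- solve_pedestrian_path(encounter_design("right", 30, 0))
  st <- relative_state(tr, 0)
  expect_equal(st$half_span_deg, asin(0.3 / 19.4) * 180 / pi, tolerance = 1e-9)
  expect_equal(asin(0.3 / 0.6) * 180 / pi, 30)   # the printed looming examples
  expect_equal(asin(0.3 / 0.523) * 180 / pi, 35, tolerance = 0.02)
  # coincident positions: distance 0, half span 90, bearing flagged
  st6 <- relative_state(tr, 6)
  expect_lt(st6$distance_m, 1e-9)
  expect_true(st6$bearing_undefined || st6$half_span_deg == 90)
})

test_that("closest approach matches the printed and derived cases", {
  par <- closest_approach(solve_pedestrian_path(encounter_design("right", 5, Inf)))
  expect_equal(par$dmin_m, 1.69, tolerance = 1e-9)
  col <- closest_approach(solve_pedestrian_path(encounter_design("right", 30, 0)))
  expect_equal(col$dmin_m, 0, tolerance = 1e-9)
  expect_equal(col$t_star_s, 6, tolerance = 1e-9)
  near <- closest_approach(solve_pedestrian_path(encounter_design("right", 10, 2)))
  expect_equal(near$dmin_m, 0.39, tolerance = 0.01)
  expect_equal(near$t_star_s, 6.68, tolerance = 0.01)
})

test_that("closed-form closest approach agrees with the 1 ms sampling oracle", {
  trials <- solve_pedestrian_path(random_designs(200, seed = 7))
  ca <- closest_approach(trials)
  for (i in seq_len(nrow(trials))) {
    oracle <- dense_closest_approach(trials[i, ])
    expect_lt(abs(ca$dmin_m[i] - oracle$dmin), 1e-4)
  }
})

test_that("field entry times match the figure-derived values", {
  col45 <- solve_pedestrian_path(encounter_design("right", 45, 0))
  expect_equal(field_entry_time(col45, 10), 5.8, tolerance = 0.05)
  par5 <- solve_pedestrian_path(encounter_design("right", 5, Inf))
  expect_equal(field_entry_time(par5, 10), 0)
  far <- solve_pedestrian_path(encounter_design("right", 30, 12))
  expect_equal(field_entry_time(far, 10), 4.4, tolerance = 0.1)
  # a pedestrian holding a 45-degree bearing never reaches a 10-degree field
  # if closest approach comes first
  away <- solve_pedestrian_path(encounter_design("right", 45, -15))
  ca <- closest_approach(away)
  if (is.na(field_entry_time(away, 10))) succeed() else {
    expect_lte(field_entry_time(away, 10), ca$t_star_s)
  }
})

test_that("disappearance happens 0.1 s before the path crossing", {
  expect_equal(disappearance_time(encounter_design("right", 10, 2)), 5.9)
  expect_equal(disappearance_time(encounter_design("right", 5, Inf)), 6.0)
  expect_equal(disappearance_time(encounter_design("right", 10, 2, t_cross_s = 0.1)), 0)
})

test_that("center-to-center courses hold a constant bearing", {
  for (side in c("left", "right")) for (b0 in c(10, 30)) {
    tr <- solve_pedestrian_path(encounter_design(side, b0, 0))
    st <- relative_state(tr, seq(0, 5.99, by = 0.01))
    expect_lt(max(abs(abs(st$bearing_center_deg) - b0)), 1e-6)
  }
})

test_that("mirroring left/right negates bearings and preserves scalars", {
  trials <- solve_pedestrian_path(random_designs(25, seed = 11))
  for (i in seq_len(nrow(trials))) {
    a <- trials[i, ]
    b <- mirror_trial(a)
    t <- seq(0, 5.9, by = 0.5)
    sa <- relative_state(a, t)
    sb <- relative_state(b, t)
    expect_equal(sb$bearing_center_deg, -sa$bearing_center_deg, tolerance = 1e-9)
    expect_equal(sb$distance_m, sa$distance_m, tolerance = 1e-9)
    expect_equal(sb$half_span_deg, sa$half_span_deg, tolerance = 1e-9)
    expect_equal(closest_approach(b)$dmin_m, closest_approach(a)$dmin_m,
                 tolerance = 1e-9)
  }
})

test_that("closest distance is non-decreasing in |dpc| within a bearing family", {
  for (b0 in c(10, 30)) {
    d <- vapply(c(0, 2, 12), function(dp) {
      closest_approach(solve_pedestrian_path(encounter_design("right", b0, dp)))$dmin_m
    }, numeric(1))
    expect_true(all(diff(d) >= 0))
    d0 <- closest_approach(solve_pedestrian_path(encounter_design("right", b0, 0)))$dmin_m
    dm2 <- closest_approach(solve_pedestrian_path(encounter_design("right", b0, -2)))$dmin_m
    expect_gte(dm2, d0)
  }
})

test_that("bearing span contains the center and looms as distance shrinks", {
  tr <- solve_pedestrian_path(encounter_design("right", 30, 2))
  st <- relative_state(tr, seq(0, 5.9, by = 0.1))
  lo <- st$bearing_center_deg - st$half_span_deg
  hi <- st$bearing_center_deg + st$half_span_deg
  expect_true(all(lo <= st$bearing_center_deg & st$bearing_center_deg <= hi))
  shrinking <- diff(st$distance_m) < 0
  expect_true(all(diff(st$half_span_deg)[shrinking] > 0))
})
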