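#' Synthetic observer parameters
#'
#' Parameters of the parametric observer used to generate detection and
#' collision-decision logs with the statistical structure the analysis
#' pipeline assumes. Detection is the first event of an inhomogeneous
#' Poisson process whose rate depends on where the pedestrian currently
#' falls in the modeled visual field (`central`, `island`, or `none`);
#' the island rate defaults lower than the central rate because the
#' prism-expanded islands are optically compressed and monocular. The
#' collision decision applies a threshold to a noisy estimate of the true
#' closest distance, with occasional lapses. Decision time shrinks as the
#' encounter becomes imminent: late detections leave little to judge.
#'
#' @param hazard_central,hazard_island,hazard_none Detection rates (events
#'   per second) while the pedestrian is in each region.
#' @param motor_latency_s Fixed response floor added to the detection event
#'   time (s).
#' @param rt_jitter_scale_s,rt_jitter_sdlog Lognormal jitter added to the
#'   detection RT: median `rt_jitter_scale_s`, log-sd `rt_jitter_sdlog`.
#' @param decision_threshold_m Perceived-collision criterion on the
#'   estimated closest distance (m).
#' @param cue_noise_m Gaussian noise sd on the closest-distance estimate (m).
#' @param lapse_rate Probability of a random (uniform) collision decision.
#' @param decision_base_s,decision_slope Decision RT model:
#'   `base + slope * (t_cross - detection event time)`, floored at 0.05 s.
#' @param rng_seed Integer seed.
#' @return A list of class `prismwalk_observer`.
#' @export
observer_params <- function(hazard_central = 2, hazard_island = 0.8,
                            hazard_none = 0,
                            motor_latency_s = 0.35,
                            rt_jitter_scale_s = 0.15, rt_jitter_sdlog = 0.25,
                            decision_threshold_m = 1.2, cue_noise_m = 0.4,
                            lapse_rate = 0.02,
                            decision_base_s = 0.3, decision_slope = 0.15,
                            rng_seed = 1L) {
  if (any(c(hazard_central, hazard_island, hazard_none) < 0)) {
    abort("Hazards must be non-negative.", class = "prismwalk_invalid_argument")
  }
  if (lapse_rate < 0 || lapse_rate >= 1) {
    abort("`lapse_rate` must lie in [0, 1).", class = "prismwalk_invalid_argument")
  }
  if (decision_threshold_m <= 0) {
    abort("`decision_threshold_m` must be positive.",
          class = "prismwalk_invalid_argument")
  }
  structure(list(
    hazard = c(central = hazard_central, island = hazard_island,
               none = hazard_none),
    motor_latency_s = motor_latency_s,
    rt_jitter_scale_s = rt_jitter_scale_s,
    rt_jitter_sdlog = rt_jitter_sdlog,
    decision_threshold_m = decision_threshold_m,
    cue_noise_m = cue_noise_m,
    lapse_rate = lapse_rate,
    decision_base_s = decision_base_s,
    decision_slope = decision_slope,
    rng_seed = as.integer(rng_seed)
  ), class = "prismwalk_observer")
}

#' Default field models for the three viewing conditions
#'
#' `NV` (normal vision) sees everywhere; `PFL` is the 20-degree residual
#' central field alone; `PFL+PR` adds the prism-expanded lateral islands.
#'
#' @param goggles,prism,scene_distance_mm Passed to [field_model()].
#' @return Named list of `prismwalk_field` objects.
#' @export
condition_fields <- function(goggles = goggle_spec(), prism = prism_spec(),
                             scene_distance_mm = 735) {
  list(
    "NV" = field_model(NULL),
    "PFL" = field_model(goggles, NULL),
    "PFL+PR" = field_model(goggles, prism, scene_distance_mm)
  )
}

# piecewise-constant region occupancy of a trial under a field model:
# tibble(region, t0, t1) partitioning [0, disappear_s]
region_segments <- function(trial, field, dt = 0.01) {
  t_end <- trial$disappear_s
  grid <- seq(0, t_end, by = dt)
  if (length(grid) < 2) grid <- c(0, t_end)
  mids <- (head(grid, -1) + grid[-1]) / 2
  reg <- classify_visibility(trial, field, mids)
  r <- rle(reg)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  tibble::tibble(
    region = r$values,
    t0 = grid[starts + 1],
    t1 = grid[ends + 1]
  )
}

#' Closed-form detection probability
#'
#' Probability that the inhomogeneous Poisson detection process fires before
#' the pedestrian disappears: `1 - exp(-sum(hazard_r * exposure_r))`.
#'
#' @param trial A one-row solved trial.
#' @param field A `prismwalk_field`.
#' @param params A [observer_params()].
#' @return Probability in [0, 1].
#' @export
detection_probability <- function(trial, field, params) {
  seg <- region_segments(trial, field)
  h <- params$hazard[seg$region]
  int <- sum(h * (seg$t1 - seg$t0))
  1 - exp(-int)
}

# sample the first event time of the piecewise-constant process, NA if none
sample_event_time <- function(seg, hazard) {
  for (i in seq_len(nrow(seg))) {
    h <- hazard[[seg$region[i]]]
    if (h == 0) next
    if (is.infinite(h)) return(seg$t0[i])
    w <- rexp(1, rate = h)
    if (w <= seg$t1[i] - seg$t0[i]) return(seg$t0[i] + w)
  }
  NA_real_
}

#' Simulate observer responses to a battery
#'
#' Generates one response record per trial under the given viewing
#' condition: whether the pedestrian was detected, the detection RT (event
#' time plus motor latency plus lognormal jitter), the collision decision
#' (threshold on the noisy closest-distance estimate, with lapses; present
#' only when detected) and the decision RT. Identical seeds give identical
#' logs.
#'
#' @param battery A solved trial tibble from [build_battery()].
#' @param params A [observer_params()].
#' @param condition `"NV"`, `"PFL"` or `"PFL+PR"`.
#' @param field Optional `prismwalk_field` overriding the condition default.
#' @param seed Integer seed; defaults to `params$rng_seed`.
#' @return A tibble with `trial_id`, `condition`, `detected`,
#'   `detection_rt_s`, `decision`, `decision_rt_s`.
#' @examples
#' simulate_responses(build_battery(1), observer_params(), "PFL")
#' @export
simulate_responses <- function(battery, params = observer_params(),
                               condition = c("NV", "PFL", "PFL+PR"),
                               field = NULL, seed = params$rng_seed) {
  condition <- match.arg(condition)
  if (is.null(field)) field <- condition_fields()[[condition]]
  ca <- closest_approach(battery)
  withr_seed(seed, {
    rows <- purrr::map(seq_len(nrow(battery)), function(i) {
      tr <- battery[i, ]
      seg <- region_segments(tr, field)
      te <- sample_event_time(seg, params$hazard)
      detected <- !is.na(te)
      rt <- decision <- drt <- NA_real_
      decision <- NA_character_
      if (detected) {
        rt <- te + params$motor_latency_s +
          rlnorm(1, meanlog = log(params$rt_jitter_scale_s),
                 sdlog = params$rt_jitter_sdlog)
        est <- ca$dmin_m[i] + rnorm(1, 0, params$cue_noise_m)
        decision <- if (est < params$decision_threshold_m) "collision" else "noncollision"
        if (runif(1) < params$lapse_rate) {
          decision <- sample(c("collision", "noncollision"), 1)
        }
        drt <- max(0.05, params$decision_base_s +
                     params$decision_slope * (tr$t_cross_s - te))
      }
      tibble::tibble(
        trial_id = tr$trial_id,
        condition = condition,
        detected = detected,
        detection_rt_s = rt,
        decision = decision,
        decision_rt_s = drt
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Estimate observer parameters from a response log
#'
#' Maximum-likelihood recovery of the region detection hazards and the
#' collision-decision threshold from simulated (or comparable) logs.
#' Detection event times are reconstructed from the detection RTs by
#' subtracting the known motor latency and the median jitter; hazards are
#' the Poisson-process MLE events/exposure per region, with standard error
#' `sqrt(events)/exposure`. The decision threshold is estimated by probit
#' regression of the collision decision on the true closest distance
#' (`threshold = -intercept/slope`, delta-method SE). When the decisions
#' separate perfectly (a noiseless observer), the probit is degenerate and
#' the boundary interval between the largest collision-judged and smallest
#' noncollision-judged closest distance is reported instead, with the
#' midpoint as estimate.
#'
#' @param log A response log from [simulate_responses()] (one or more
#'   conditions row-bound together).
#' @param battery The battery the log was generated from.
#' @param fields Named list of field models per condition, as
#'   [condition_fields()].
#' @param motor_latency_s,rt_jitter_scale_s Known response-floor components
#'   subtracted from detection RTs.
#' @return An object of class `prismwalk_observer_fit` with elements
#'   `hazards`, `threshold`, `decision_model` (the probit fit or `NULL`),
#'   and `n_trials`.
#' @export
estimate_observer <- function(log, battery, fields = condition_fields(),
                              motor_latency_s = 0.35,
                              rt_jitter_scale_s = 0.15) {
  if (!any(log$detected)) {
    abort("No detections in the log; hazards are not estimable.",
          class = "prismwalk_estimation_failure")
  }
  joined <- dplyr::inner_join(log, closest_approach(battery),
                              by = "trial_id")
  if (nrow(joined) != nrow(log)) {
    abort("Some responses do not join a battery trial.",
          class = "prismwalk_join_error")
  }
  events <- exposure <- c(central = 0, island = 0, none = 0)
  for (i in seq_len(nrow(joined))) {
    tr <- joined[i, ]
    field <- fields[[tr$condition]]
    seg <- region_segments(dplyr::select(tr, -dplyr::any_of("condition")), field)
    if (tr$detected) {
      te <- min(max(0, tr$detection_rt_s - motor_latency_s - rt_jitter_scale_s),
                tr$disappear_s)
      cut <- seg[seg$t0 < te, , drop = FALSE]
      cut$t1 <- pmin(cut$t1, te)
      reg_at <- seg$region[findInterval(te, seg$t0)]
      events[reg_at] <- events[reg_at] + 1
      seg <- cut
    }
    for (r in unique(seg$region)) {
      exposure[r] <- exposure[r] + sum(seg$t1[seg$region == r] - seg$t0[seg$region == r])
    }
  }
  hazards <- tibble::tibble(
    region = names(events),
    events = as.numeric(events),
    exposure_s = as.numeric(exposure),
    estimate = ifelse(exposure > 0, events / exposure, NA_real_),
    se = ifelse(exposure > 0, sqrt(events) / exposure, NA_real_)
  )

  dec <- joined[joined$detected & !is.na(joined$decision), , drop = FALSE]
  threshold <- tibble::tibble(estimate = NA_real_, se = NA_real_,
                              lo = NA_real_, hi = NA_real_, separated = NA)
  model <- NULL
  if (nrow(dec) >= 2 && length(unique(dec$decision)) == 2) {
    y <- as.integer(dec$decision == "collision")
    coll_max <- suppressWarnings(max(dec$dmin_m[y == 1]))
    nonc_min <- suppressWarnings(min(dec$dmin_m[y == 0]))
    if (coll_max < nonc_min) {
      # perfect separation: report the boundary interval
      threshold <- tibble::tibble(
        estimate = (coll_max + nonc_min) / 2, se = (nonc_min - coll_max) / 4,
        lo = coll_max, hi = nonc_min, separated = TRUE
      )
    } else {
      model <- suppressWarnings(
        glm(y ~ dmin_m, family = binomial("probit"), data = dec)
      )
      a <- coef(model)[1]
      b <- coef(model)[2]
      V <- vcov(model)
      est <- -a / b
      g <- c(-1 / b, a / b^2)
      se <- sqrt(drop(t(g) %*% V %*% g))
      threshold <- tibble::tibble(estimate = unname(est), se = se,
                                  lo = NA_real_, hi = NA_real_,
                                  separated = FALSE)
    }
  }
  structure(list(hazards = hazards, threshold = threshold,
                 decision_model = model, n_trials = nrow(log)),
            class = "prismwalk_observer_fit")
}

#' @export
print.prismwalk_observer_fit <- function(x, ...) {
  cat("Observer fit over", x$n_trials, "trials\n")
  print(x$hazards)
  cat("Decision threshold:\n")
  print(x$threshold)
  invisible(x)
}

#' Tidy an observer fit
#'
#' @param x A `prismwalk_observer_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`, `std.error`).
#' @export
tidy.prismwalk_observer_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = paste0("hazard_", x$hazards$region),
                   estimate = x$hazards$estimate,
                   std.error = x$hazards$se),
    tibble::tibble(term = "decision_threshold_m",
                   estimate = x$threshold$estimate,
                   std.error = x$threshold$se)
  )
}

#' Glance at an observer fit
#'
#' @param x A `prismwalk_observer_fit`.
#' @param ... Unused.
#' @return One-row tibble with trial count, total detections and, when a
#'   probit decision model was fit, its deviance against the null deviance.
#' @export
glance.prismwalk_observer_fit <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_detections = sum(x$hazards$events),
    threshold_separated = x$threshold$separated,
    deviance = if (is.null(x$decision_model)) NA_real_ else x$decision_model$deviance,
    null_deviance = if (is.null(x$decision_model)) NA_real_ else x$decision_model$null.deviance
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
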