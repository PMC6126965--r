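#' Grouped detection, decision and RT summaries
#'
#' Joins a response log to its battery and summarizes per viewing condition
#' and field-position group. Trials are grouped by whether the pedestrian's
#' initial bearing exceeded 10 degrees: `central` (initial bearing <= 10
#' degrees, inclusive, inside the residual central field) versus
#' `peripheral`. Detection rate is over all trials; collision-decision
#' accuracy (decision matching the designed truth label) is computed among
#' detected trials only; RT means are over responded trials.
#'
#' @param log A response log (one or more conditions bound together).
#' @param battery The solved battery tibble the log refers to.
#' @return A tibble with one row per condition x field group:
#'   `detection_rate_pct`, `decision_accuracy_pct`, `mean_detection_rt_s`,
#'   `mean_decision_rt_s`, `n_trials`.
#' @examples
#' b <- build_battery(1)
#' summarize_responses(simulate_responses(b, condition = "PFL"), b)
#' @export
summarize_responses <- function(log, battery) {
  joined <- dplyr::inner_join(log, battery, by = "trial_id")
  if (nrow(joined) != nrow(log)) {
    abort("Some responses do not join a battery trial.",
          class = "prismwalk_join_error")
  }
  joined |>
    dplyr::mutate(field_group = ifelse(.data$beta0_deg <= 10,
                                       "central", "peripheral")) |>
    dplyr::group_by(.data$condition, .data$field_group) |>
    dplyr::summarise(
      detection_rate_pct = 100 * mean(.data$detected),
      decision_accuracy_pct = if (any(.data$detected)) {
        100 * mean(.data$decision[.data$detected] ==
                     .data$truth[.data$detected], na.rm = TRUE)
      } else NA_real_,
      mean_detection_rt_s = mean(.data$detection_rt_s[.data$detected]),
      mean_decision_rt_s = mean(.data$decision_rt_s[.data$detected], na.rm = TRUE),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Correlation of perceived collision with the candidate visual cues
#'
#' Aggregates the log to the designed conditions (initial bearing x
#' path-crossing distance, collapsed over sides, as the per-condition points
#' of the cue scatterplots), computes the percent of detected trials judged
#' as collisions per condition, and correlates it with the per-condition
#' accumulated bearing deviation (expected negative), bearing-span overlap
#' (expected positive) and closest distance (expected negative).
#'
#' @param log A response log.
#' @param battery The battery the log refers to.
#' @param cues Per-trial cue table from [compute_cues()].
#' @return A tibble with one row per cue: `cue`, `r`, `r_squared`, `n_conditions`.
#'   Errors with class `prismwalk_undefined` if the perceived-collision
#'   percentage has no variance across conditions.
#' @export
cue_response_correlation <- function(log, battery, cues = compute_cues(battery)) {
  joined <- dplyr::inner_join(log, battery, by = "trial_id") |>
    dplyr::inner_join(
      cues |> dplyr::select("trial_id", "abd_deg", "overlap_pct", "dmin_m"),
      by = "trial_id"
    )
  agg <- joined |>
    dplyr::filter(.data$detected, !is.na(.data$decision)) |>
    dplyr::group_by(.data$beta0_deg, .data$dpc_m) |>
    dplyr::summarise(
      perceived_collision_pct = 100 * mean(.data$decision == "collision"),
      abd_deg = mean(.data$abd_deg),
      overlap_pct = mean(.data$overlap_pct),
      dmin_m = mean(.data$dmin_m),
      .groups = "drop"
    )
  if (nrow(agg) < 3) {
    abort("Fewer than 3 designed conditions with decisions.",
          class = "prismwalk_undefined")
  }
  if (stats::sd(agg$perceived_collision_pct) == 0) {
    abort("Perceived collision has zero variance across conditions.",
          class = "prismwalk_undefined")
  }
  one <- function(cue) {
    x <- agg[[cue]]
    if (stats::sd(x) == 0) {
      abort(paste0("Cue `", cue, "` has zero variance across conditions."),
            class = "prismwalk_undefined")
    }
    r <- cor(agg$perceived_collision_pct, x)
    tibble::tibble(cue = cue, r = r, r_squared = r^2, n_conditions = nrow(agg))
  }
  dplyr::bind_rows(one("abd_deg"), one("overlap_pct"), one("dmin_m"))
}

#' Plot grouped summaries
#'
#' Bar charts of detection rate and decision accuracy per condition and
#' field group, mirroring the grouped-results layout.
#'
#' @param summary A tibble from [summarize_responses()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("detection_rate_pct", "decision_accuracy_pct"),
                        names_to = "measure", values_to = "pct")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$condition, y = .data$pct,
                               fill = .data$field_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(y = "%", x = NULL, fill = "field position") +
    ggplot2::theme_minimal()
}

#' Plot cue-response scatter
#'
#' Per-condition percent perceived collision against each cue.
#'
#' @param log,battery,cues As in [cue_response_correlation()].
#' @return A ggplot object.
#' @export
plot_cue_response <- function(log, battery, cues = compute_cues(battery)) {
  joined <- dplyr::inner_join(log, battery, by = "trial_id") |>
    dplyr::inner_join(
      cues |> dplyr::select("trial_id", "abd_deg", "overlap_pct", "dmin_m"),
      by = "trial_id"
    ) |>
    dplyr::filter(.data$detected, !is.na(.data$decision)) |>
    dplyr::group_by(.data$beta0_deg, .data$dpc_m) |>
    dplyr::summarise(
      perceived_collision_pct = 100 * mean(.data$decision == "collision"),
      abd_deg = mean(.data$abd_deg), overlap_pct = mean(.data$overlap_pct),
      dmin_m = mean(.data$dmin_m), .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("abd_deg", "overlap_pct", "dmin_m"),
                        names_to = "cue", values_to = "value")
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data$value,
                               y = .data$perceived_collision_pct)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cue, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "perceived collision (%)") +
    ggplot2::theme_minimal()
}
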