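battery_csv_cols <- c(
  "trial_id", "segment_index", "battery_seed", "side", "beta0_deg", "dpc_m",
  "d0_m", "t_cross_s", "participant_speed_mps", "body_diameter_m",
  "parallel_offset_m", "dpc_convention", "start_x_m", "start_y_m",
  "heading_deg", "speed_mps", "disappear_s", "truth"
)

#' Write and read battery manifests
#'
#' Batteries are serialized either as flat CSV (one row per trial, units in
#' the column names, UTF-8, '.' decimal) or as nested JSON. Infinite
#' path-crossing distances (parallel encounters) are written as the string
#' `"Inf"` in JSON and `Inf` in CSV. Reading validates the schema and
#' reproduces the numeric columns to full double precision.
#'
#' @param battery A battery tibble from [build_battery()].
#' @param path Output file path (`.csv` or `.json`).
#' @return `write_battery()` returns `path` invisibly; `read_battery()`
#'   returns the battery tibble.
#' @export
write_battery <- function(battery, path) {
  missing <- setdiff(battery_csv_cols, names(battery))
  if (length(missing) > 0) {
    abort(paste("Battery is missing columns:", paste(missing, collapse = ", ")),
          class = "prismwalk_parse_error")
  }
  out <- battery[battery_csv_cols]
  if (grepl("\\.json$", path)) {
    # JSON has no Inf literal: carry the parallel sentinel as the string "Inf"
    out$dpc_m <- as.character(out$dpc_m)
    jsonlite::write_json(out, path, digits = NA, na = "null", pretty = TRUE)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_battery
#' @export
read_battery <- function(path) {
  if (grepl("\\.json$", path)) {
    df <- jsonlite::fromJSON(path)
    df <- tibble::as_tibble(df)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            trial_id = "c", side = "c",
                            dpc_convention = "c", truth = "c",
                            .default = "d"
                          ))
    df$segment_index <- as.integer(df$segment_index)
    df$battery_seed <- as.integer(df$battery_seed)
  }
  missing <- setdiff(battery_csv_cols, names(df))
  if (length(missing) > 0) {
    abort(paste("File lacks battery columns:", paste(missing, collapse = ", ")),
          class = "prismwalk_parse_error")
  }
  df$dpc_m <- as.numeric(df$dpc_m)
  df$segment_index <- as.integer(df$segment_index)
  df$battery_seed <- as.integer(df$battery_seed)
  validate_design(df)
  df[battery_csv_cols]
}

#' Write and read response logs
#'
#' Response logs are flat CSV with one row per trial response. Reading
#' validates that every row has a trial id and a detection flag, and that a
#' decision is present only for detected trials; violations report the
#' offending row.
#'
#' @param log A response tibble from [simulate_responses()].
#' @param path Output CSV path.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   returns the log tibble.
#' @export
write_responses <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          trial_id = "c", condition = "c", detected = "l",
                          detection_rt_s = "d", decision = "c",
                          decision_rt_s = "d"
                        ))
  need <- c("trial_id", "condition", "detected", "detection_rt_s",
            "decision", "decision_rt_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste("File lacks response columns:", paste(missing, collapse = ", ")),
          class = "prismwalk_parse_error")
  }
  bad <- which(is.na(df$trial_id) | is.na(df$detected))
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], " has a missing trial id or detection flag."),
          class = "prismwalk_parse_error")
  }
  bad <- which(df$detected & is.na(df$decision))
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], " is detected but has no decision."),
          class = "prismwalk_parse_error")
  }
  bad <- which(!df$detected & !is.na(df$decision))
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], " has a decision without a detection."),
          class = "prismwalk_parse_error")
  }
  tibble::as_tibble(df)
}
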