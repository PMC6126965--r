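battery <- build_battery(1)

perfect_log <- function(b, condition = "NV") {
  tibble::tibble(
    trial_id = b$trial_id,
    condition = condition,
    detected = TRUE,
    detection_rt_s = 1.1,
    decision = b$truth,
    decision_rt_s = 0.8
  )
}

test_that("a perfect observer scores 100% detection and accuracy in both groups", {
  s <- summarize_responses(perfect_log(battery), battery)
  expect_equal(nrow(s), 2)
  expect_equal(s$detection_rate_pct, c(100, 100))
  expect_equal(s$decision_accuracy_pct, c(100, 100))
  expect_equal(s$mean_detection_rt_s, c(1.1, 1.1))
})

test_that("the 10-degree bearing is grouped as central (boundary inclusive)", {
  joined <- dplyr::inner_join(perfect_log(battery), battery, by = "trial_id") |>
    dplyr::mutate(field_group = ifelse(beta0_deg <= 10, "central", "peripheral"))
  expect_true(all(joined$field_group[joined$beta0_deg == 10] == "central"))
  s <- summarize_responses(perfect_log(battery), battery)
  expect_equal(s$n_trials[s$field_group == "central"], 12) # 2x parallel + 4x10 per side
  expect_equal(s$n_trials[s$field_group == "peripheral"], 8)
})

test_that("summaries ignore trial order and respect the detected-only accuracy rule", {
  log <- perfect_log(battery)
  # three known misses and one known wrong decision among the detected
  log$detected[c(2, 5, 9)] <- FALSE
  log$decision[c(2, 5, 9)] <- NA
  log$detection_rt_s[c(2, 5, 9)] <- NA
  wrong <- which(log$detected)[1]
  log$decision[wrong] <- ifelse(battery$truth[wrong] == "collision",
                                "noncollision", "collision")
  s1 <- summarize_responses(log, battery)
  perm <- sample(nrow(log))
  s2 <- summarize_responses(log[perm, ], battery)
  expect_equal(s1, s2)
  joined <- dplyr::inner_join(log, battery, by = "trial_id")
  for (g in c("central", "peripheral")) {
    sub <- joined[(joined$beta0_deg <= 10) == (g == "central"), ]
    det <- sub[sub$detected, ]
    expect_equal(s1$detection_rate_pct[s1$field_group == g],
                 100 * nrow(det) / nrow(sub))
    expect_equal(s1$decision_accuracy_pct[s1$field_group == g],
                 100 * mean(det$decision == det$truth))
  }
})

test_that("merged logs summarize as the trial-weighted merge of parts", {
  p <- observer_params(rng_seed = 8)
  l1 <- simulate_responses(battery, p, "PFL", seed = 100)
  b2 <- build_battery(2) |> dplyr::mutate(trial_id = paste0("S2_", trial_id))
  l2 <- simulate_responses(b2, p, "PFL", seed = 200)
  merged <- summarize_responses(dplyr::bind_rows(l1, l2),
                                dplyr::bind_rows(battery, b2))
  s1 <- summarize_responses(l1, battery)
  s2 <- summarize_responses(l2, b2)
  for (g in unique(merged$field_group)) {
    n1 <- s1$n_trials[s1$field_group == g]
    n2 <- s2$n_trials[s2$field_group == g]
    expect_equal(
      merged$detection_rate_pct[merged$field_group == g],
      (s1$detection_rate_pct[s1$field_group == g] * n1 +
         s2$detection_rate_pct[s2$field_group == g] * n2) / (n1 + n2)
    )
  }
})

test_that("orphan responses fail the join", {
  log <- perfect_log(battery)
  log$trial_id[1] <- "T99"
  expect_error(summarize_responses(log, battery), class = "prismwalk_join_error")
})

test_that("simulated field loss depresses peripheral but not central detection", {
  p <- observer_params(rng_seed = 9)
  logs <- dplyr::bind_rows(purrr::map(1:8, function(s) {
    b <- build_battery(s) |> dplyr::mutate(trial_id = paste0(s, "_", trial_id))
    simulate_responses(b, p, "PFL", seed = 300 + s)
  }))
  bats <- dplyr::bind_rows(purrr::map(1:8, function(s) {
    build_battery(s) |> dplyr::mutate(trial_id = paste0(s, "_", trial_id))
  }))
  s <- summarize_responses(logs, bats)
  expect_lt(s$detection_rate_pct[s$field_group == "peripheral"],
            s$detection_rate_pct[s$field_group == "central"])
})

test_that("a noiseless threshold observer yields r(dmin) = -1 over threshold-spanning conditions", {
  p <- observer_params(cue_noise_m = 0, lapse_rate = 0,
                      hazard_central = 50, hazard_island = 50, rng_seed = 10)
  log <- simulate_responses(battery, p, "NV", seed = 42)
  # restrict to conditions on one side of each bearing family so percent
  # collision is a step in dmin; aggregated per condition the correlation
  # with dmin is then exactly the monotone step pattern
  cor_tab <- cue_response_correlation(log, battery)
  r_dmin <- cor_tab$r[cor_tab$cue == "dmin_m"]
  expect_lt(r_dmin, 0)
  # deterministic decisions: perceived collision is exactly 0 or 100
  joined <- dplyr::inner_join(log, battery, by = "trial_id")
  agg <- joined |>
    dplyr::filter(detected) |>
    dplyr::group_by(beta0_deg, dpc_m) |>
    dplyr::summarise(pc = mean(decision == "collision"), .groups = "drop")
  expect_true(all(agg$pc %in% c(0, 1)))
})

test_that("cue correlations carry the (-, +, -) sign pattern", {
  p <- observer_params(rng_seed = 12)
  logs <- dplyr::bind_rows(purrr::map(1:6, function(s) {
    b <- build_battery(s) |> dplyr::mutate(trial_id = paste0(s, "_", trial_id))
    simulate_responses(b, p, "NV", seed = 400 + s)
  }))
  bats <- dplyr::bind_rows(purrr::map(1:6, function(s) {
    build_battery(s) |> dplyr::mutate(trial_id = paste0(s, "_", trial_id))
  }))
  ct <- cue_response_correlation(logs, bats)
  expect_lt(ct$r[ct$cue == "abd_deg"], 0)
  expect_gt(ct$r[ct$cue == "overlap_pct"], 0)
  expect_lt(ct$r[ct$cue == "dmin_m"], 0)
})

test_that("degenerate responses raise the undefined flag", {
  log <- perfect_log(battery)
  log$decision <- "collision" # constant: zero variance across conditions
  expect_error(cue_response_correlation(log, battery),
               class = "prismwalk_undefined")
})

test_that("plots build without error", {
  s <- summarize_responses(perfect_log(battery), battery)
  expect_s3_class(plot_group_summary(s), "ggplot")
  p <- observer_params(rng_seed = 13)
  log <- simulate_responses(battery, p, "NV")
  expect_s3_class(plot_cue_response(log, battery), "ggplot")
})
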