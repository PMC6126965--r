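# dense-sampling oracle for the closest approach of two constant-velocity
# agents: evaluates |relative position| on a 1 ms grid
dense_closest_approach <- function(trial, dt = 0.001, t_max = 30) {
  h <- trial$heading_deg * pi / 180
  vx <- trial$speed_mps * sin(h)
  vy <- trial$speed_mps * cos(h) - trial$participant_speed_mps
  repeat {
    t <- seq(0, t_max, by = dt)
    d <- sqrt((trial$start_x_m + vx * t)^2 + (trial$start_y_m + vy * t)^2)
    i <- which.min(d)
    if (i < length(t) || t_max > 1e4) break
    t_max <- t_max * 2 # separation still shrinking at the horizon: extend
  }
  list(t = t[i], dmin = d[i])
}

# random feasible crossing designs for property tests (continuous ranges
# spanning the battery's conditions; near-zero crossing distances excluded so
# the grid oracle's resolution bound holds)
random_designs <- function(n, seed = 42) {
  set.seed(seed)
  dpc <- runif(n, -3, 12)
  dpc[abs(dpc) < 0.2] <- 0.2
  encounter_design(
    side = sample(c("left", "right"), n, replace = TRUE),
    beta0_deg = runif(n, 2, 60),
    dpc_m = dpc,
    d0_m = runif(n, 10, 25),
    t_cross_s = runif(n, 4, 8)
  )
}

mirror_trial <- function(trial) {
  trial$side <- ifelse(trial$side == "left", "right", "left")
  trial$start_x_m <- -trial$start_x_m
  trial$heading_deg <- prismwalk:::norm_deg(-trial$heading_deg)
  trial
}
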