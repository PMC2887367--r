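# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default-subject session through the full five-phase protocol, scaled to
# 12 proper turns per phase to keep the run fast
cached_session <- function() {
  fixture("session", {
    proto <- session_protocol(n_proper_turns = 12,
                              catch_trials_per_field_set = 6)
    simulate_session(proto, subject_params(seed = 42), task_config())
  })
}

cached_lap_table <- function() {
  fixture("laps", lap_table(cached_session(), task_config()))
}

# field-only session with the subject already adapted: the steady-state
# bench for catch-trial estimator checks
cached_ff_session <- function(gain = 0.8, seed = 3) {
  key <- sprintf("ff_%s_%d", gain, seed)
  fixture(key, {
    proto <- session_protocol(
      phases = tibble::tibble(name = c("FF1", "FF2"), field_on = TRUE),
      n_proper_turns = 15, catch_trials_per_field_set = 10)
    simulate_session(proto,
                     subject_params(compensation_gain = gain, seed = seed),
                     task_config(), start_adapted = TRUE)
  })
}

# --- independent oracles ----------------------------------------------------

# brute-force submovement segmentation: same contract as
# segment_submovements(circular = FALSE), written as a direct O(n^2) scan
bf_segment_count <- function(speed, min_prominence_frac = 0.02) {
  n <- length(speed)
  floor_val <- min_prominence_frac * max(speed)
  mins <- integer(0)
  for (i in 2:(n - 1)) {
    if (speed[i] < speed[i - 1]) {
      j <- i
      while (j < n && speed[j + 1] == speed[j]) j <- j + 1
      if (j < n && speed[j + 1] > speed[j]) mins <- c(mins, i)
    }
  }
  keep <- integer(0)
  for (i in mins) {
    lo <- speed[i]
    left <- -Inf
    for (j in rev(seq_len(i - 1))) {
      if (speed[j] < lo) break
      left <- max(left, speed[j])
    }
    right <- -Inf
    for (j in seq(i + 1, n)) {
      if (speed[j] < lo) break
      right <- max(right, speed[j])
    }
    if (min(left, right) - lo >= floor_val) keep <- c(keep, i)
  }
  length(unique(c(1L, keep, n))) - 1L
}

# random smooth non-negative signal for segmentation property tests
random_smooth_speed <- function(n = 120) {
  x <- stats::filter(rnorm(n + 40), rep(1 / 8, 8), sides = 1)
  x <- x[!is.na(x)][seq_len(n)]
  x - min(x) + 0.05
}

# minimal synthetic two-lap log built directly from the errorless lap
errorless_log <- function(n_laps = 2, cfg = task_config(), fs = cfg$fs) {
  il <- ideal_lap(cfg, n_samples = cfg$T_lap * fs)
  rows <- purrr::map(seq_len(n_laps), function(k) {
    tibble::tibble(
      t = il$t + (k - 1) * cfg$T_lap,
      target_x = il$x, target_y = il$y,
      hand_x = il$x, hand_y = il$y,
      field_on = 0L, catch = 0L, phase = "FA1", lap = k,
      alpha = il$alpha + (k - 1) * 2 * pi)
  })
  log <- dplyr::bind_rows(rows)
  class(log) <- c("trajectory_log", class(log))
  attr(log, "cfg") <- cfg
  log
}
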