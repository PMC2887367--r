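cfg <- task_config()
params <- subject_params(seed = 1)

test_that("a submovement plan toward a stationary on-hand target is constant", {
  st <- target_state(1, cfg, alpha_dot = 0)
  hand <- list(position = st$position, velocity = c(0, 0))
  ref <- plan_submovement(hand, st, params, cfg, noise = FALSE)
  expect_lt(max(abs(ref$x - st$position[1])), 1e-12)
  expect_lt(max(abs(ref$y - st$position[2])), 1e-12)
  expect_lt(max(abs(ref$vx)), 1e-12)
})

test_that("planned endpoints scatter with the configured planning noise", {
  set.seed(99)
  st <- target_state(0.7, cfg)
  hand <- list(position = st$position, velocity = st$velocity)
  clean <- plan_submovement(hand, st, params, cfg, noise = FALSE)
  ends <- replicate(3000, {
    ref <- plan_submovement(hand, st, params, cfg, noise = TRUE)
    c(utils::tail(ref$x, 1), utils::tail(ref$y, 1))
  })
  dx <- ends[1, ] - utils::tail(clean$x, 1)
  dy <- ends[2, ] - utils::tail(clean$y, 1)
  expect_equal(sd(dx), params$plan_noise_sd, tolerance = 0.06)
  expect_equal(sd(dy), params$plan_noise_sd, tolerance = 0.06)
})

test_that("arm impedance settles at the Hooke displacement under load", {
  f <- c(12, -5)
  ref <- list(position = c(0, 0), velocity = c(0, 0))
  st <- list(position = c(0, 0), velocity = c(0, 0))
  for (i in 1:3000) st <- step_arm(st, ref, f, c(0, 0), params, 1e-3)
  expect_equal(st$position, f / params$stiffness, tolerance = 1e-6)

  # perfect cancellation reproduces the unforced trajectory exactly
  ref2 <- list(position = c(0.05, 0.02), velocity = c(0, 0))
  a <- list(position = c(0, 0), velocity = c(0, 0))
  b <- a
  for (i in 1:500) {
    a <- step_arm(a, ref2, c(3, -7), c(-3, 7), params, 1e-2)
    b <- step_arm(b, ref2, c(0, 0), c(0, 0), params, 1e-2)
  }
  expect_equal(a$position, b$position, tolerance = 1e-10)
  expect_equal(a$velocity, b$velocity, tolerance = 1e-10)
})

test_that("a 12 N lateral ramp leaves a 2 cm steady deviation at K = 600", {
  ref <- list(position = c(0, 0), velocity = c(0, 0))
  st <- list(position = c(0, 0), velocity = c(0, 0))
  for (i in 1:4000) {
    fr <- min(i / 1000, 1) * c(0, 12)
    st <- step_arm(st, ref, fr, c(0, 0), params, 1e-3)
  }
  expect_equal(st$position[2], 12 / 600, tolerance = 1e-4)
})

test_that("commanded compensation mirrors the curl disturbance", {
  expect_equal(commanded_compensation(c(0.2, 0.1), subject_params(compensation_gain = 0),
                                      cfg), c(0, 0))
  v <- c(0.07, -0.11)
  full <- commanded_compensation(v, subject_params(compensation_gain = 1), cfg)
  expect_equal(full + curl_force(v, cfg), c(0, 0), tolerance = 1e-12)
  fc <- commanded_compensation(c(0.12, 0), subject_params(compensation_gain = 0.8), cfg)
  expect_equal(sqrt(sum(fc^2)), 9.6, tolerance = 1e-12)
  expect_equal(commanded_compensation(v, params, cfg, believes_field_on = FALSE),
               c(0, 0))
})

test_that("sessions are deterministic given the seed", {
  proto <- session_protocol(n_proper_turns = 2, catch_trials_per_field_set = 2)
  a <- simulate_session(proto, subject_params(seed = 5), cfg)
  b <- simulate_session(proto, subject_params(seed = 5), cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_session(proto, subject_params(seed = 6), cfg)
  expect_false(identical(a$hand_x, c$hand_x))
})

test_that("the session log respects the protocol structure", {
  log <- cached_session()
  expect_true(all(diff(log$t) - 0.01 < 1e-9))
  expect_true(!is.unsorted(log$lap))
  # catch windows only inside field phases, with the field actually off
  expect_true(all(log$phase[log$catch == 1] %in% c("FF1", "FF2")))
  expect_true(all(log$field_on[log$catch == 1] == 0))
  expect_true(all(log$field_on[log$phase %in% c("FA1", "FA2", "WO")] == 0))
  # every phase completed its proper-turn quota
  laps <- cached_lap_table()
  per_phase <- dplyr::count(dplyr::filter(laps, proper), phase)
  expect_true(all(per_phase$n >= 12))
})

test_that("a near-perfect adapted subject satisfies the 2 cm task tolerance", {
  proto <- session_protocol(phases = tibble::tibble(name = "FF1", field_on = TRUE),
                            n_proper_turns = 5, catch_trials_per_field_set = 0)
  good <- subject_params(compensation_gain = 1, stiffness = 2400,
                         plan_noise_sd = 0, seed = 2)
  log <- simulate_session(proto, good, cfg, start_adapted = TRUE)
  laps <- lap_table(log, cfg)
  expect_true(all(laps$delta < 0.02))
})

test_that("field phases show the adaptation phenomenology", {
  laps <- cached_lap_table()
  agg <- laps %>%
    dplyr::group_by(grp = sub("[0-9]$", "", phase)) %>%
    dplyr::summarise(dn = mean(delta_n), NP = mean(NP), .groups = "drop")
  dn_fa <- agg$dn[agg$grp == "FA"]
  expect_lt(abs(dn_fa), 1e-3)                     # unbiased without field
  expect_gt(agg$dn[agg$grp == "FF"], 0)           # rightward bias under field
  expect_gt(agg$NP[agg$grp == "FF"], agg$NP[agg$grp == "FA"])
})
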