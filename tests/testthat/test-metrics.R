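cfg <- task_config()

test_that("error decomposition projects onto the travel frame", {
  lap <- ideal_lap(cfg, 800)
  same <- error_decomposition(lap, lap)
  expect_true(all(abs(same$e) < 1e-12))

  ahead <- dplyr::mutate(lap, x = x + 0.01 * vx / speed, y = y + 0.01 * vy / speed)
  err <- error_decomposition(ahead, lap)
  expect_equal(err$e_l, rep(0.01, 800), tolerance = 1e-9)
  expect_lt(max(abs(err$e_n)), 1e-9)

  # rotation oracle: displace 1 cm rightward of travel for random headings
  set.seed(21)
  for (i in 1:100) {
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    right <- c(u[2], -u[1])
    target <- tibble::tibble(x = 0, y = 0, vx = 0.1 * u[1], vy = 0.1 * u[2])
    hand <- tibble::tibble(x = 0.01 * right[1], y = 0.01 * right[2])
    err <- error_decomposition(hand, target)
    expect_equal(err$e_n, 0.01, tolerance = 1e-12)
    expect_lt(abs(err$e_l), 1e-12)
  }
})

test_that("the travel frame reconstructs the raw error vector exactly", {
  log <- cached_session()
  hand <- smooth_and_differentiate(log[1:3000, c("hand_x", "hand_y")], 100)
  target <- smooth_and_differentiate(log[1:3000, c("target_x", "target_y")], 100)
  err <- error_decomposition(hand, target)
  sp <- sqrt(target$vx^2 + target$vy^2)
  ok <- sp > 1e-4
  ux <- target$vx[ok] / sp[ok]; uy <- target$vy[ok] / sp[ok]
  rx <- err$e_l[ok] * ux + err$e_n[ok] * uy
  ry <- err$e_l[ok] * uy - err$e_n[ok] * ux
  expect_equal(rx, (hand$x - target$x)[ok], tolerance = 1e-12)
  expect_equal(ry, (hand$y - target$y)[ok], tolerance = 1e-12)
  expect_equal(err$e[ok]^2, err$e_l[ok]^2 + err$e_n[ok]^2, tolerance = 1e-12)
})

test_that("figural error is a symmetric, rigid-motion-invariant shape distance", {
  th <- seq(0, 2 * pi, length.out = 400)
  c1 <- cbind(0.10 * cos(th), 0.10 * sin(th))
  c2 <- cbind(0.11 * cos(th), 0.11 * sin(th))
  expect_equal(figural_error(c1, c1), 0, tolerance = 1e-12)
  expect_equal(figural_error(c1, c2), 0.01, tolerance = 1e-4)
  expect_identical(figural_error(c1, c2), figural_error(c2, c1))

  # resampling one path at half the rate barely moves the value
  half <- c2[seq(1, 400, by = 2), ]
  expect_lt(abs(figural_error(c1, half) - figural_error(c1, c2)), 1e-4)

  # rigid motion applied to both paths leaves it unchanged
  phi <- 0.6; R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  shift <- c(0.3, -0.2)
  m1 <- sweep(c1 %*% t(R), 2, shift, "+")
  m2 <- sweep(c2 %*% t(R), 2, shift, "+")
  expect_equal(figural_error(m1, m2), figural_error(c1, c2), tolerance = 1e-12)
  expect_error(figural_error(c1[1, , drop = FALSE], c2), "2 points")
})

test_that("speed-curvature coupling of the errorless lap is 0.91", {
  lap <- ideal_lap(cfg, 2000)
  expect_equal(speed_curvature_correlation(lap), 0.91, tolerance = 0.01)
  # exact proportionality gives 1
  fake <- tibble::tibble(speed = runif(300, 0.05, 0.2))
  fake$curvature <- 3 * fake$speed
  expect_equal(speed_curvature_correlation(fake), 1, tolerance = 1e-12)
  # independent noise decorrelates
  set.seed(8)
  for (i in 1:5) {
    nn <- tibble::tibble(speed = rnorm(800, 0.1, 0.02),
                         curvature = rnorm(800, 5, 1))
    expect_lt(speed_curvature_correlation(nn), 0.15)
  }
  expect_true(is.na(speed_curvature_correlation(
    tibble::tibble(speed = rep(0.1, 100), curvature = rep(2, 100)))))
})

test_that("lateral deviation is signed rightward-of-travel off the ideal path", {
  lap <- ideal_lap(cfg, 400)
  on_path <- lateral_deviation(lap, cfg, alpha = lap$alpha)
  expect_lt(max(abs(on_path)), 1e-5)

  # offset along the local rightward normal
  tl <- sqrt(lap$vx^2 + lap$vy^2)
  nx <- lap$vy / tl; ny <- -lap$vx / tl
  off <- tibble::tibble(x = lap$x + 0.005 * nx, y = lap$y + 0.005 * ny)
  ld <- lateral_deviation(off, cfg, alpha = lap$alpha)
  expect_lt(max(abs(ld - 0.005)), 2e-5)

  # leftward offset flips the sign
  ld2 <- lateral_deviation(tibble::tibble(x = lap$x - 0.005 * nx,
                                          y = lap$y - 0.005 * ny),
                           cfg, alpha = lap$alpha)
  expect_lt(max(abs(ld2 + 0.005)), 2e-5)
})

test_that("lateral deviation tracks the normal error on field laps", {
  log <- cached_session()
  ff <- log[log$phase == "FF2", ]
  hand <- smooth_and_differentiate(ff[, c("hand_x", "hand_y")], 100)
  target <- smooth_and_differentiate(ff[, c("target_x", "target_y")], 100)
  ld <- lateral_deviation(hand, cfg, alpha = ff$alpha)
  en <- error_decomposition(hand, target)$e_n
  expect_gt(cor(ld, en), 0.9)
})

test_that("force-movement correlation behaves at its edge cases", {
  sp <- runif(200, 0.05, 0.2)
  expect_true(is.na(force_movement_correlation(sp, rep(0.01, 200))))
  expect_equal(force_movement_correlation(sp, 0.3 * sp + 0.01), 1, tolerance = 1e-12)
  expect_error(force_movement_correlation(sp, sp[-1]), "lengths differ")
})

test_that("force-movement coupling falls as compensation approaches the disturbance", {
  # residual lateral force scales with (1 - gain) * speed, so the speed-LD
  # correlation must drop sharply between partial and full compensation
  full <- lap_table(cached_ff_session(gain = 1.0, seed = 3), cfg)
  part <- lap_table(cached_ff_session(gain = 0.8, seed = 3), cfg)
  expect_lt(mean(full$FMC, na.rm = TRUE), 0.25)
  expect_lt(mean(part$FMC, na.rm = TRUE), 0.55)
  expect_gt(mean(part$FMC, na.rm = TRUE), mean(full$FMC, na.rm = TRUE))
})

test_that("the lap table summarises an errorless log correctly", {
  log <- errorless_log(2)
  laps <- lap_table(log, cfg)
  expect_identical(nrow(laps), 2L)
  expect_equal(laps$DUR, c(8, 8), tolerance = 0.01)
  expect_true(all(laps$delta < 1e-6))
  expect_true(all(laps$proper))
  expect_true(all(laps$NP == 4))
  expect_equal(laps$CC, c(0.91, 0.91), tolerance = 0.015)
})

test_that("slow turns are flagged as failed", {
  log1 <- errorless_log(1)
  # second lap traversed at reduced rate: 13 s for the full circuit
  slow <- ideal_lap(cfg, 1300)
  log2 <- tibble::tibble(
    t = max(log1$t) + 0.01 + (seq_len(1300) - 1) / 100,
    target_x = slow$x, target_y = slow$y,
    hand_x = slow$x, hand_y = slow$y,
    field_on = 0L, catch = 0L, phase = "FA1", lap = 2L,
    alpha = slow$alpha + 2 * pi)
  log <- dplyr::bind_rows(tibble::as_tibble(log1), log2)
  attr(log, "cfg") <- cfg
  laps <- lap_table(log, cfg)
  expect_true(laps$proper[1])
  expect_false(laps$proper[2])
  expect_equal(laps$DUR[2], 13, tolerance = 0.01)
})

test_that("lap metrics depend only on each lap's own samples", {
  log <- cached_session()
  first_phase <- log[log$phase %in% c("FA1", "FA2"), ]
  laps <- lap_table(first_phase, cfg)
  # rebuild the log with the two phase blocks swapped
  a <- log[log$phase == "FA1", ]; b <- log[log$phase == "FA2", ]
  swapped <- dplyr::bind_rows(b, a)
  swapped$t <- (seq_len(nrow(swapped)) - 1) / 100
  attr(swapped, "cfg") <- cfg
  laps2 <- lap_table(swapped, cfg)
  for (col in c("delta", "delta_n", "FE", "NP", "CC", "LD_mean", "FMC")) {
    expect_equal(sort(laps2[[col]]), sort(laps[[col]]), tolerance = 1e-9)
  }
})

test_that("phase summary aggregates with standard errors", {
  laps <- cached_lap_table()
  ps <- phase_summary(laps)
  expect_true(all(c("phase", "indicator", "mean", "sd", "se", "n") %in% names(ps)))
  one <- dplyr::filter(ps, phase == "FA1", indicator == "delta")
  raw <- dplyr::filter(laps, phase == "FA1", proper)$delta
  expect_equal(one$mean, mean(raw))
  expect_equal(one$se, sd(raw) / sqrt(length(raw)))
})
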