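cfg <- task_config()

test_that("Lissajous map hits its landmark points and analytic derivative", {
  p <- lissajous_point(c(0, pi / 2, pi), cfg)
  expect_equal(p$x, c(0, 0.157, 0), tolerance = 1e-12)
  expect_equal(p$y, c(0, 0, 0), tolerance = 1e-12)
  # derivative against central differences at random phases
  a <- runif(50, 0, 2 * pi)
  h <- 1e-6
  num_dx <- (lissajous_point(a + h, cfg)$x - lissajous_point(a - h, cfg)$x) / (2 * h)
  num_dy <- (lissajous_point(a + h, cfg)$y - lissajous_point(a - h, cfg)$y) / (2 * h)
  pa <- lissajous_point(a, cfg)
  expect_equal(pa$dx_dalpha, num_dx, tolerance = 1e-6)
  expect_equal(pa$dy_dalpha, num_dy, tolerance = 1e-6)
})

test_that("one lap of the eight-shape is 1.02 m long", {
  # independent oracle: adaptive quadrature of the speed w.r.t. alpha
  arc <- stats::integrate(function(a) {
    p <- lissajous_point(a, cfg)
    sqrt(p$dx_dalpha^2 + p$dy_dalpha^2)
  }, 0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(arc, 1.02, tolerance = 0.01)
  expect_equal(ideal_lap_summary(cfg)$arc_length_m, arc, tolerance = 1e-5)
})

test_that("speed gain is a minimum-jerk step through the gate", {
  expect_identical(speed_gain(0, cfg), 1)
  expect_identical(speed_gain(cfg$D / 2, cfg), 0.5)
  expect_identical(speed_gain(cfg$D, cfg), 0)
  expect_identical(speed_gain(0.5, cfg), 0)
  # monotone non-increasing, C1 at both ends
  e <- seq(0, 0.08, by = 1e-4)
  g <- speed_gain(e, cfg)
  expect_true(all(diff(g) <= 1e-12))
  expect_true(all(g >= 0 & g <= 1))
  h <- 1e-6
  expect_lt(abs((speed_gain(h, cfg) - 1) / h), 1e-3)
  expect_lt(abs(speed_gain(cfg$D - h, cfg) / h), 1e-3)
  expect_error(speed_gain(-0.01, cfg), "non-negative")
})

test_that("target advance integrates the gated phase dynamics", {
  dt <- 1 / cfg$fs
  # perfect tracking: one lap in T seconds
  st <- target_state(0, cfg)
  n <- 0
  while (st$alpha < 2 * pi) {
    st <- advance_target(st, st$position, dt, cfg)
    n <- n + 1
  }
  expect_equal(n * dt, cfg$T_lap, tolerance = dt * 1.5)

  # hand at the gate: target frozen
  st2 <- advance_target(target_state(1, cfg),
                        lissajous_point(1, cfg) %>%
                          with(c(x + 0.08, y)), dt, cfg)
  expect_equal(st2$alpha, 1)
  expect_equal(st2$velocity, c(0, 0))

  # constant 3 cm error: lap takes 2 T
  st <- target_state(0, cfg)
  n <- 0
  while (st$alpha < 2 * pi) {
    st <- advance_target(st, st$position + c(0, 0.03), dt, cfg)
    n <- n + 1
  }
  expect_equal(n * dt, 2 * cfg$T_lap, tolerance = 2 * dt)
})

test_that("lap duration under perfect tracking is invariant to the step size", {
  lap_time <- function(dt) {
    st <- target_state(0, cfg)
    n <- 0
    while (st$alpha < 2 * pi) {
      st <- advance_target(st, st$position, dt, cfg)
      n <- n + 1
    }
    n * dt
  }
  expect_equal(lap_time(0.01), lap_time(0.002), tolerance = 0.011)
})

test_that("errorless lap reproduces the printed reference quantities", {
  s <- ideal_lap_summary(cfg)
  expect_lt(abs(s$speed_max_ms - 0.188), 0.001)
  expect_lt(abs(s$speed_min_ms - 0.083), 0.001)
  expect_identical(s$n_speed_peaks, 4L)
  expect_lt(s$accel_max_ms2, 0.3)
  # closed-form oracle for the speed extrema: optimize the alpha expression
  w <- 2 * pi / cfg$T_lap
  spd <- function(a) w * sqrt(cfg$A^2 * cos(a)^2 + 4 * cfg$B^2 * cos(2 * a)^2)
  vmax <- stats::optimize(spd, c(-0.5, 0.5), maximum = TRUE)$objective
  vmin <- stats::optimize(spd, c(0.5, 1.5))$objective
  expect_lt(abs(s$speed_max_ms - vmax), 1e-5)
  expect_lt(abs(s$speed_min_ms - vmin), 1e-5)
  # acceleration oracle likewise
  acc <- function(a) w^2 * sqrt(cfg$A^2 * sin(a)^2 + 16 * cfg$B^2 * sin(2 * a)^2)
  amax <- stats::optimize(acc, c(1, 2.5), maximum = TRUE)$objective
  expect_equal(s$accel_max_ms2, amax, tolerance = 1e-3)
})

test_that("ideal lap derivatives are analytic, not filtered", {
  lap <- ideal_lap(cfg, 500)
  w <- 2 * pi / cfg$T_lap
  expect_equal(lap$vx, cfg$A * w * cos(lap$alpha), tolerance = 1e-12)
  expect_equal(lap$ay, -4 * cfg$B * w^2 * sin(2 * lap$alpha), tolerance = 1e-12)
  expect_error(ideal_lap(cfg, 50), "at least 100")
})

test_that("curl force is a pure clockwise rotation scaled by b", {
  expect_equal(curl_force(c(0.188, 0), cfg), c(0, -18.8), tolerance = 1e-12)
  expect_equal(curl_force(c(0, 0), cfg), c(0, 0))
  expect_equal(curl_force(c(0.1, -0.2), cfg, field_on = FALSE), c(0, 0))
  v <- matrix(rnorm(2e4), ncol = 2)
  f <- curl_force(v, cfg)
  expect_lt(max(abs(rowSums(f * v))) / cfg$b, 1e-13)     # F . v = 0
  expect_equal(sqrt(rowSums(f^2)), cfg$b * sqrt(rowSums(v^2)), tolerance = 1e-12)
  # rightward of travel: for v = +x the force points to -y
  expect_lt(curl_force(c(1, 0), cfg)[2], 0)
})
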