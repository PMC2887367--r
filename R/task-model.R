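#' Point on the eight-shaped target path
#'
#' The target path is a 1:2 Lissajous figure parameterized by the phase angle
#' `alpha`:
#' \deqn{x = A \sin\alpha, \qquad y = B \sin 2\alpha}
#' with the crossing point at the origin, x rightward and y away from the
#' subject. The analytic derivative with respect to `alpha` is returned
#' alongside the position so speed, acceleration and curvature of the ideal
#' trajectory can be computed without numerical differentiation.
#'
#' @param alpha Phase angle (rad), any length.
#' @param cfg A [task_config()].
#' @return A tibble with columns `alpha`, `x`, `y`, `dx_dalpha`, `dy_dalpha`.
#' @examples
#' lissajous_point(c(0, pi / 2), task_config())
#' @export
lissajous_point <- function(alpha, cfg = task_config()) {
  tibble(alpha = alpha,
         x = cfg$A * sin(alpha),
         y = cfg$B * sin(2 * alpha),
         dx_dalpha = cfg$A * cos(alpha),
         dy_dalpha = 2 * cfg$B * cos(2 * alpha))
}

# second derivative of the Lissajous map w.r.t. alpha (internal)
lissajous_dd <- function(alpha, cfg) {
  cbind(-cfg$A * sin(alpha), -4 * cfg$B * sin(2 * alpha))
}

#' Error-dependent angular-speed gain
#'
#' The target's angular speed is modulated by the instantaneous tracking
#' error `e = |hand - target|`: the gain falls smoothly from 1 at zero error
#' to 0 at the threshold `D`, following a minimum-jerk step
#' \deqn{\gamma(e) = 1 - (10 s^3 - 15 s^4 + 6 s^5), \quad s = e / D}
#' so that \eqn{\gamma(D/2) = 0.5} exactly and the target stops (and waits)
#' whenever the error reaches `D`.
#'
#' @param e Tracking error (m), non-negative, any length.
#' @param cfg A [task_config()].
#' @return Gain values in `[0, 1]`, same length as `e`.
#' @examples
#' speed_gain(c(0, 0.03, 0.06), task_config())
#' @export
speed_gain <- function(e, cfg = task_config()) {
  if (any(e < 0)) abort("tracking error `e` must be non-negative.")
  s <- pmin(e / cfg$D, 1)
  1 - (10 * s^3 - 15 * s^4 + 6 * s^5)
}

#' Advance the target one time step
#'
#' Integrates the gated target dynamics by one explicit-Euler step:
#' \deqn{\dot\alpha = \gamma(e) \, 2\pi / T}
#' where `e` is the distance from the hand to the current target position.
#' The returned state carries the target position and velocity (chain rule
#' through \eqn{\dot\alpha}) and the lap index `floor(alpha / 2 pi)`.
#'
#' @param state A target state as returned by [target_state()] or a previous
#'   call to `advance_target()`.
#' @param hand_position Numeric length-2 hand position (m).
#' @param dt Time step (s), positive.
#' @param cfg A [task_config()].
#' @return An updated target state (class `target_state`).
#' @export
advance_target <- function(state, hand_position, dt, cfg = task_config()) {
  if (dt <= 0) abort("`dt` must be positive.")
  e <- sqrt(sum((hand_position - state$position)^2))
  rate <- speed_gain(e, cfg) * 2 * pi / cfg$T_lap
  target_state(state$alpha + rate * dt, cfg, alpha_dot = rate)
}

#' @rdname advance_target
#' @param alpha Phase angle (rad).
#' @param alpha_dot Current angular rate (rad/s) used for the velocity.
#' @export
target_state <- function(alpha = 0, cfg = task_config(),
                         alpha_dot = 2 * pi / cfg$T_lap) {
  p <- lissajous_point(alpha, cfg)
  structure(
    list(alpha = alpha,
         position = c(p$x, p$y),
         velocity = c(p$dx_dalpha, p$dy_dalpha) * alpha_dot,
         lap_index = floor(alpha / (2 * pi))),
    class = "target_state"
  )
}

#' Ideal errorless lap
#'
#' Samples one lap of the target under perfect tracking (gain identically 1,
#' so `alpha = 2 pi t / T`) uniformly in time. Velocity, acceleration, speed
#' and signed curvature are computed analytically from the Lissajous
#' parameterization, not by filtering, so the result serves as the errorless
#' reference for every indicator: speed range 8.3-18.8 cm/s, four speed peaks
#' per lap, peak acceleration below 0.3 m/s^2, and a speed-to-|curvature|
#' correlation magnitude of 0.91.
#'
#' @param cfg A [task_config()].
#' @param n_samples Number of samples over the lap (at least 100).
#' @return A tibble of class `ideal_lap` with columns `t`, `alpha`, `x`, `y`,
#'   `vx`, `vy`, `ax`, `ay`, `speed`, `curvature`.
#' @examples
#' lap <- ideal_lap(task_config())
#' range(lap$speed)
#' @export
ideal_lap <- function(cfg = task_config(), n_samples = 2000) {
  if (n_samples < 100) abort("`n_samples` must be at least 100.")
  t <- seq(0, cfg$T_lap, length.out = n_samples + 1)[seq_len(n_samples)]
  w <- 2 * pi / cfg$T_lap
  alpha <- w * t
  p <- lissajous_point(alpha, cfg)
  dd <- lissajous_dd(alpha, cfg)
  vx <- p$dx_dalpha * w
  vy <- p$dy_dalpha * w
  ax <- dd[, 1] * w^2
  ay <- dd[, 2] * w^2
  speed <- sqrt(vx^2 + vy^2)
  out <- tibble(t = t, alpha = alpha, x = p$x, y = p$y,
                vx = vx, vy = vy, ax = ax, ay = ay,
                speed = speed,
                curvature = (vx * ay - vy * ax) / speed^3)
  class(out) <- c("ideal_lap", class(out))
  attr(out, "cfg") <- cfg
  out
}

#' Reference quantities of the errorless lap
#'
#' Computes the analytic benchmarks of the ideal lap: arc length, speed
#' extrema, peak acceleration, number of speed peaks (counted circularly over
#' the closed lap), the magnitude of the speed-|curvature| correlation, the
#' peak curl-field force at the configured viscosity, and the peak inertial
#' force at a given equivalent mass.
#'
#' @param cfg A [task_config()].
#' @param mass Equivalent endpoint mass for the inertial-force estimate (kg).
#' @param n_samples Sampling density for the quadrature and extrema search.
#' @return A one-row tibble with columns `arc_length_m`, `speed_min_ms`,
#'   `speed_max_ms`, `accel_max_ms2`, `n_speed_peaks`,
#'   `speed_curvature_corr`, `force_max_N`, `force_min_N`,
#'   `inertial_force_max_N`.
#' @examples
#' ideal_lap_summary(task_config())
#' @export
ideal_lap_summary <- function(cfg = task_config(), mass = 2.0,
                              n_samples = 20000) {
  lap <- ideal_lap(cfg, n_samples)
  # arc length by trapezoid quadrature of |dp/dalpha| over a closed period
  alpha <- c(lap$alpha, 2 * pi)
  p <- lissajous_point(alpha, cfg)
  g <- sqrt(p$dx_dalpha^2 + p$dy_dalpha^2)
  arc <- sum((g[-1] + g[-length(g)]) / 2 * diff(alpha))
  np <- count_peaks_circular(lap$speed)
  tibble(arc_length_m = arc,
         speed_min_ms = min(lap$speed),
         speed_max_ms = max(lap$speed),
         accel_max_ms2 = max(sqrt(lap$ax^2 + lap$ay^2)),
         n_speed_peaks = np,
         speed_curvature_corr = abs(cor(lap$speed, abs(lap$curvature))),
         force_max_N = cfg$b * max(lap$speed),
         force_min_N = cfg$b * min(lap$speed),
         inertial_force_max_N = mass * max(sqrt(lap$ax^2 + lap$ay^2)))
}

# strict local maxima of a periodic series, counted once per period
count_peaks_circular <- function(x) {
  n <- length(x)
  xl <- x[c(n, seq_len(n - 1))]
  xr <- x[c(seq_len(n - 1) + 1, 1)]
  sum(x > xl & x >= xr)
}

#' Curl viscous disturbance force
#'
#' When the field is on, the disturbance is the velocity rotated 90 degrees
#' clockwise (to the right of travel in an x-right, y-up frame) and scaled by
#' the viscosity:
#' \deqn{F = b \, (v_y, -v_x)}
#' so `|F| = b |v|` and `F . v = 0`: the field does no mechanical work on the
#' velocity it is computed from, it only deviates the hand sideways.
#'
#' @param velocity Numeric length-2 velocity (m/s), or an n-by-2 matrix.
#' @param cfg A [task_config()].
#' @param field_on Logical; if `FALSE` the force is identically zero.
#' @return Force (N) with the same shape as `velocity`.
#' @examples
#' curl_force(c(0.188, 0), task_config())
#' @export
curl_force <- function(velocity, cfg = task_config(), field_on = TRUE) {
  if (!field_on) {
    z <- velocity
    z[] <- 0
    return(z)
  }
  if (is.matrix(velocity)) {
    cbind(cfg$b * velocity[, 2], -cfg$b * velocity[, 1])
  } else {
    c(cfg$b * velocity[2], -cfg$b * velocity[1])
  }
}
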