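# Minimum-jerk quintic from (p0, v0, acc 0) to (p1, v1, acc 0) over duration Tp.
# Returns a 6 x d coefficient matrix for the local-time polynomial
# sum_k c[k+1] * t^k, one column per spatial dimension.
minjerk_coefs <- function(p0, v0, p1, v1, Tp) {
  dp <- p1 - p0
  c3 <- (10 * dp - (6 * v0 + 4 * v1) * Tp) / Tp^3
  c4 <- (-15 * dp + (8 * v0 + 7 * v1) * Tp) / Tp^4
  c5 <- (6 * dp - 3 * (v0 + v1) * Tp) / Tp^5
  rbind(p0, v0, 0, c3, c4, c5, deparse.level = 0)
}

minjerk_eval <- function(cf, tt) {
  pos <- cf[1, ] + tt * (cf[2, ] + tt * (cf[3, ] + tt * (cf[4, ] +
         tt * (cf[5, ] + tt * cf[6, ]))))
  vel <- cf[2, ] + tt * (2 * cf[3, ] + tt * (3 * cf[4, ] +
         tt * (4 * cf[5, ] + tt * 5 * cf[6, ])))
  list(pos = pos, vel = vel)
}

#' Plan one intermittent submovement
#'
#' The simulated subject controls the hand intermittently: at `replan_rate`
#' Hz it commits to a fresh minimum-jerk reference segment that starts from
#' the current hand state and lands on the target's predicted position (and
#' velocity) one replan interval ahead. The landing point is corrupted by
#' isotropic Gaussian planning noise of sd `plan_noise_sd`, which is what
#' makes the simulated speed profiles pulsatile at the replanning frequency.
#'
#' @param current_hand A list with numeric length-2 `position` (m) and
#'   `velocity` (m/s).
#' @param target_state A [target_state()].
#' @param params A [subject_params()].
#' @param cfg A [task_config()].
#' @param noise Logical; set `FALSE` for the noiseless planned reference.
#' @return A tibble with columns `t`, `x`, `y`, `vx`, `vy` sampling the
#'   reference segment at the task rate over one replan interval.
#' @export
plan_submovement <- function(current_hand, target_state, params,
                             cfg = task_config(), noise = TRUE) {
  Tp <- 1 / params$replan_rate
  adot <- sqrt(sum(target_state$velocity^2))
  gdot <- sqrt(sum(lissajous_point(target_state$alpha, cfg)[
    , c("dx_dalpha", "dy_dalpha")]^2))
  alpha_rate <- if (gdot > 0) adot / gdot else 0
  alpha_pred <- target_state$alpha + alpha_rate * Tp
  p <- lissajous_point(alpha_pred, cfg)
  p1 <- c(p$x, p$y)
  v1 <- params$hold_fraction_vel * c(p$dx_dalpha, p$dy_dalpha) * alpha_rate
  if (noise) p1 <- p1 + rnorm(2, sd = params$plan_noise_sd)
  cf <- minjerk_coefs(current_hand$position, current_hand$velocity, p1, v1, Tp)
  tt <- seq(0, Tp, by = 1 / cfg$fs)
  ref <- vapply(tt, function(x) unlist(minjerk_eval(cf, x)), numeric(4))
  tibble(t = tt, x = ref[1, ], y = ref[2, ], vx = ref[3, ], vy = ref[4, ])
}

#' Integrate the arm-impedance dynamics one step
#'
#' The arm plus handle is modelled as a point mass coupled to the planned
#' reference through endpoint stiffness and damping:
#' \deqn{m \ddot{x} = K (x_r - x) + B (\dot{x}_r - \dot{x}) + F_C + F_{ext}}
#' integrated with a semi-implicit Euler step. In the static limit this is
#' the quasi-static force balance used by the catch-trial decomposition: a
#' constant external force displaces the hand by `F / K` from its reference.
#'
#' @param hand_state List with `position` and `velocity` (length-2 numerics).
#' @param reference List with `position` and `velocity` of the planned
#'   reference at this instant.
#' @param external_force Numeric length-2 external force (N).
#' @param commanded_force Numeric length-2 voluntary force command (N).
#' @param params A [subject_params()].
#' @param dt Time step (s).
#' @return Updated `hand_state` list.
#' @export
step_arm <- function(hand_state, reference, external_force, commanded_force,
                     params, dt) {
  if (dt <= 0) abort("`dt` must be positive.")
  acc <- (params$stiffness * (reference$position - hand_state$position) +
          params$damping * (reference$velocity - hand_state$velocity) +
          commanded_force + external_force) / params$mass
  v <- hand_state$velocity + acc * dt
  list(position = hand_state$position + v * dt, velocity = v)
}

#' Feedforward compensation force
#'
#' The adapted subject commands a force that mirrors the curl disturbance
#' computed from its own hand velocity, scaled by the compensation gain:
#' `F_C = -gain * b * (v_y, -v_x)`. The command follows the subject's belief
#' about the field, not its actual state, so it stays on during unannounced
#' catch trials -- which is exactly what makes the hand overshoot to the left
#' of the path and renders the commanded force observable.
#'
#' @param hand_velocity Numeric length-2 hand velocity (m/s).
#' @param params A [subject_params()].
#' @param cfg A [task_config()].
#' @param believes_field_on Logical belief state.
#' @param gain Effective gain to use; defaults to the asymptotic
#'   `params$compensation_gain`.
#' @return Numeric length-2 force (N).
#' @export
commanded_compensation <- function(hand_velocity, params, cfg = task_config(),
                                   believes_field_on = TRUE,
                                   gain = params$compensation_gain) {
  if (!believes_field_on) return(c(0, 0))
  -gain * curl_force(hand_velocity, cfg, field_on = TRUE)
}

#' Simulate a full tracking session
#'
#' Runs the simulated subject through the whole protocol at the task sample
#' rate and returns the 100 Hz trajectory log with phase, lap, field and
#' catch-window annotations -- the same table an experimental recording would
#' produce. Adaptation is emulated by a first-order ramp of the commanded
#' gain toward `compensation_gain` with lap constant `tau_adapt` while the
#' field is on, decaying with lap constant `tau_washout` once it is removed;
#' catch trials leave the commanded gain untouched because the subject cannot
#' anticipate them. Each field-on phase carries the scheduled catch trials:
#' the field is silently switched off for `catch_duration` seconds when the
#' target crosses the figure's central point, provided the tracking error at
#' the crossing is below `catch_error_gate`.
#'
#' @param protocol A [session_protocol()].
#' @param params A [subject_params()].
#' @param cfg A [task_config()].
#' @param start_adapted Logical; if `TRUE` the commanded gain starts at its
#'   asymptote on entering each field-on phase (no ramp), which isolates the
#'   steady-state estimators from the learning transient.
#' @return A tibble of class `trajectory_log` with columns `t`, `target_x`,
#'   `target_y`, `hand_x`, `hand_y`, `field_on`, `catch`, `phase`, `lap`,
#'   `alpha`. The task config, subject parameters, protocol and seed travel
#'   along as attributes.
#' @examples
#' proto <- session_protocol(n_proper_turns = 2, catch_trials_per_field_set = 0)
#' log <- simulate_session(proto, subject_params(seed = 7), task_config())
#' dplyr::count(log, phase)
#' @export
simulate_session <- function(protocol = session_protocol(),
                             params = subject_params(),
                             cfg = task_config(),
                             start_adapted = FALSE) {
  set.seed(params$seed)
  dt <- 1 / cfg$fs
  w0 <- 2 * pi / cfg$T_lap
  Tp <- 1 / params$replan_rate
  K <- params$stiffness; Bd <- params$damping; m <- params$mass
  ginf <- params$compensation_gain
  b <- cfg$b
  use_hand_vel <- identical(cfg$field_velocity_source, "hand")

  # growable column buffers
  cap <- 262144L
  col <- function() numeric(cap)
  buf <- list(t = col(), tx = col(), ty = col(), hx = col(), hy = col(),
              fon = col(), cat = col(), lap = col(), al = col())
  phase_id <- integer(cap)
  i <- 0L
  push <- function() {
    if (i > cap) {
      cap <<- cap * 2L
      buf <<- lapply(buf, function(v) { length(v) <- cap; v })
      length(phase_id) <<- cap
    }
  }

  alpha <- 0; t <- 0
  hp <- c(0, 0); hv <- c(0, 0)
  g_cur <- 0
  lap_global <- 0L

  new_plan <- function() {
    e <- sqrt(sum((hp - lp_pos(alpha, cfg))^2))
    adot <- speed_gain(e, cfg) * w0
    ap <- alpha + adot * Tp
    p1 <- lp_pos(ap, cfg) + rnorm(2, sd = params$plan_noise_sd)
    # partial step-and-hold: the submovement lands on the predicted target
    # point carrying only a fraction of the target's velocity, so the
    # reference speed pulses coherently at the replanning rate
    v1 <- params$hold_fraction_vel * lp_dp(ap, cfg) * adot
    minjerk_coefs(hp, hv, p1, v1, Tp)
  }

  for (ph in seq_len(nrow(protocol$phases))) {
    phase_name <- protocol$phases$name[ph]
    phase_field <- protocol$phases$field_on[ph]
    if (phase_field && start_adapted) g_cur <- ginf
    alpha0 <- alpha
    # catch-trial schedule: crossing phase angles within this set
    catch_alphas <- numeric(0)
    nc <- if (phase_field) protocol$catch_trials_per_field_set else 0L
    if (nc > 0) {
      pool <- 2:max(2, protocol$n_proper_turns)
      laps_pick <- pool[sample.int(length(pool), min(nc, length(pool)))]
      n_right <- ceiling(length(laps_pick) / 2)
      half <- c(rep(0, n_right), rep(1, length(laps_pick) - n_right))
      catch_alphas <- sort(alpha0 + (laps_pick - 1) * 2 * pi + half * pi)
    }
    catch_until <- -Inf
    proper <- 0L; lap_in_phase <- 0L
    lap_start_t <- t
    next_crossing <- alpha0 + 2 * pi
    plan <- new_plan(); plan_t0 <- t

    repeat {
      tpos <- lp_pos(alpha, cfg)
      e <- sqrt((hp[1] - tpos[1])^2 + (hp[2] - tpos[2])^2)
      adot <- speed_gain(e, cfg) * w0
      in_catch <- phase_field && t < catch_until - 1e-9
      field_now <- phase_field && !in_catch

      i <- i + 1L; push()
      buf$t[i] <- t; buf$tx[i] <- tpos[1]; buf$ty[i] <- tpos[2]
      buf$hx[i] <- hp[1]; buf$hy[i] <- hp[2]
      buf$fon[i] <- as.numeric(field_now); buf$cat[i] <- as.numeric(in_catch)
      buf$lap[i] <- lap_global + 1L; buf$al[i] <- alpha
      phase_id[i] <- ph

      # commanded-gain ramp on a lap clock
      g_target <- if (phase_field) ginf else 0
      tau <- if (g_target >= g_cur) params$tau_adapt else params$tau_washout
      g_cur <- g_cur + (g_target - g_cur) * (adot * dt / (2 * pi)) / tau

      vsrc <- if (use_hand_vel) hv else lp_dp(alpha, cfg) * adot
      fx <- 0; fy <- 0
      if (field_now) { fx <- b * vsrc[2]; fy <- -b * vsrc[1] }

      tl <- min(t - plan_t0, Tp)
      ref <- minjerk_eval(plan, tl)
      # feedforward compensation mirrors the disturbance expected along the
      # planned movement, so it stays on task during catch windows
      if (g_cur > 0) {
        fx <- fx - g_cur * b * ref$vel[2]
        fy <- fy + g_cur * b * ref$vel[1]
      }
      acc <- (K * (ref$pos - hp) + Bd * (ref$vel - hv) + c(fx, fy)) / m
      hv <- hv + acc * dt
      hp <- hp + hv * dt

      alpha_new <- alpha + adot * dt

      # catch triggers at scheduled crossings
      while (length(catch_alphas) && catch_alphas[1] <= alpha_new) {
        if (catch_alphas[1] > alpha && e < protocol$catch_error_gate) {
          catch_until <- t + dt + protocol$catch_duration
        }
        catch_alphas <- catch_alphas[-1]
      }

      t <- t + dt
      done <- FALSE
      if (alpha_new >= next_crossing) {
        lap_global <- lap_global + 1L
        lap_in_phase <- lap_in_phase + 1L
        dur <- t - lap_start_t; lap_start_t <- t
        if (dur < protocol$failed_turn_threshold) proper <- proper + 1L
        next_crossing <- next_crossing + 2 * pi
        if (proper >= protocol$n_proper_turns) done <- TRUE
        if (lap_in_phase > 4L * protocol$n_proper_turns)
          abort(sprintf("phase %s did not reach %d proper turns",
                        phase_name, protocol$n_proper_turns))
      }
      alpha <- alpha_new
      if (done) break
      if (t - plan_t0 >= Tp - 1e-9) { plan <- new_plan(); plan_t0 <- t }
    }
  }

  idx <- seq_len(i)
  out <- tibble(
    t = buf$t[idx],
    target_x = buf$tx[idx], target_y = buf$ty[idx],
    hand_x = buf$hx[idx], hand_y = buf$hy[idx],
    field_on = as.integer(buf$fon[idx]),
    catch = as.integer(buf$cat[idx]),
    phase = protocol$phases$name[phase_id[idx]],
    lap = as.integer(buf$lap[idx]),
    alpha = buf$al[idx]
  )
  class(out) <- c("trajectory_log", class(out))
  attr(out, "cfg") <- cfg
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- params$seed
  out
}

# fast scalar helpers for the simulation loop
lp_pos <- function(alpha, cfg) {
  c(cfg$A * sin(alpha), cfg$B * sin(2 * alpha))
}
lp_dp <- function(alpha, cfg) {
  c(cfg$A * cos(alpha), 2 * cfg$B * cos(2 * alpha))
}
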