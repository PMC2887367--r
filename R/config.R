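#' Task configuration for the eight-shaped tracking task
#'
#' Bundles every constant that defines the tracking task: the Lissajous
#' amplitudes, the nominal circling period, the error gate that freezes the
#' target, the curl-field viscosity and the sampling rate. Defaults reproduce
#' the standard experimental setup: a figure eight +/-15.7 cm wide and
#' +/-9 cm high (total path length about 102 cm), an 8 s nominal lap, a 6 cm
#' error threshold and a 100 N s/m curl field sampled at 100 Hz.
#'
#' @param A Horizontal half-amplitude of the figure eight (m).
#' @param B Vertical half-amplitude (m). Must satisfy `A > B > 0`.
#' @param T_lap Nominal circling period of one lap under errorless tracking (s).
#' @param D Tracking-error threshold at which the target stops (m).
#' @param b Viscous coefficient of the curl disturbance field (N s/m).
#' @param fs Sampling rate of logs and simulation (Hz).
#' @param field_velocity_source Velocity the curl field acts on: the measured
#'   hand velocity (`"hand"`, a standard curl viscous field) or the target's
#'   own velocity (`"target"`). The two coincide for errorless tracking.
#' @param speed_floor Speed (m/s) below which curvature samples are flagged
#'   invalid.
#' @param min_prominence_frac Prominence floor for submovement boundaries,
#'   as a fraction of the lap's maximum speed.
#'
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$A
#' @export
task_config <- function(A = 0.157, B = 0.09, T_lap = 8, D = 0.06, b = 100,
                        fs = 100, field_velocity_source = c("hand", "target"),
                        speed_floor = 1e-3, min_prominence_frac = 0.02) {
  field_velocity_source <- match.arg(field_velocity_source)
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(T_lap), is.numeric(D),
            is.numeric(b), is.numeric(fs))
  if (!(A > B && B > 0)) abort("`A > B > 0` is required for the figure eight.")
  if (T_lap <= 0) abort("`T_lap` must be positive.")
  if (D <= 0) abort("`D` must be positive.")
  if (b < 0) abort("`b` must be non-negative.")
  if (fs <= 0) abort("`fs` must be positive.")
  structure(
    list(A = A, B = B, T_lap = T_lap, D = D, b = b, fs = fs,
         field_velocity_source = field_velocity_source,
         speed_floor = speed_floor,
         min_prominence_frac = min_prominence_frac),
    class = "task_config"
  )
}

#' Simulated-subject parameters
#'
#' Parameters of the synthetic subject: a second-order arm impedance (mass,
#' endpoint stiffness, damping) driven by an intermittent minimum-jerk
#' planner, plus a feedforward compensation gain for the curl field.
#' The subject replans a minimum-jerk submovement toward the predicted target
#' position at `replan_rate` Hz, matching the ~1.6 Hz intermittency seen in
#' human tracking. `compensation_gain` is the asymptotic fraction of the
#' disturbance force that is actively commanded; the remainder is absorbed by
#' limb stiffness, so it is the ground truth that catch-trial PAC estimates
#' should recover.
#'
#' @param mass Equivalent endpoint mass of arm plus handle (kg).
#' @param stiffness Endpoint stiffness K (N/m).
#' @param damping Endpoint damping (N s/m); defaults to critical damping
#'   `2 * sqrt(stiffness * mass)`.
#' @param compensation_gain Asymptotic feedforward gain in `[0, 1]`.
#' @param replan_rate Submovement replanning rate (Hz).
#' @param hold_fraction_vel Fraction of the predicted target velocity carried
#'   at the landing point of each planned submovement. 1 gives perfectly
#'   velocity-matched (smooth) tracking; 0 gives pure step-and-hold. The
#'   default 0.8 makes the reference speed pulse coherently at the
#'   replanning rate, as intermittent manual tracking does.
#' @param plan_noise_sd Isotropic Gaussian noise on each planned endpoint (m).
#' @param tau_adapt Lap constant of the first-order rise of the commanded
#'   gain after field onset (laps).
#' @param tau_washout Lap constant of the gain decay after field removal (laps).
#' @param seed Integer seed; all stochasticity in a session flows from it.
#'
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(mass = 2.0, stiffness = 600,
                           damping = 2 * sqrt(stiffness * mass),
                           compensation_gain = 0.8, replan_rate = 1.6,
                           hold_fraction_vel = 0.8,
                           plan_noise_sd = 0.002, tau_adapt = 9.4,
                           tau_washout = 1.3, seed = 1L) {
  if (mass <= 0) abort("`mass` must be positive.")
  if (stiffness <= 0) abort("`stiffness` must be positive.")
  if (damping < 0) abort("`damping` must be non-negative.")
  if (compensation_gain < 0 || compensation_gain > 1)
    abort("`compensation_gain` must lie in [0, 1].")
  if (replan_rate <= 0) abort("`replan_rate` must be positive.")
  if (hold_fraction_vel < 0 || hold_fraction_vel > 1)
    abort("`hold_fraction_vel` must lie in [0, 1].")
  if (tau_adapt <= 0 || tau_washout <= 0)
    abort("adaptation lap constants must be positive.")
  structure(
    list(mass = mass, stiffness = stiffness, damping = damping,
         compensation_gain = compensation_gain, replan_rate = replan_rate,
         hold_fraction_vel = hold_fraction_vel,
         plan_noise_sd = plan_noise_sd, tau_adapt = tau_adapt,
         tau_washout = tau_washout, seed = as.integer(seed)),
    class = "subject_params"
  )
}

#' Session protocol
#'
#' Defines the ordered experimental phases and the catch-trial schedule. The
#' default protocol is two familiarization sets (FA1, FA2, field off), two
#' field sets (FF1, FF2, field on), and one wash-out set (WO, field off),
#' each run until 30 proper turns (laps completed in under 12 s). Field sets
#' carry 6 catch trials each: unannounced 0.5 s field switch-offs at the
#' figure's crossing point, half on rightward and half on leftward crossings,
#' armed only when the tracking error at the crossing is below 2 cm.
#'
#' @param phases A data frame with columns `name` (character) and `field_on`
#'   (logical), one row per phase, in order.
#' @param n_proper_turns Proper turns required to complete each phase.
#' @param catch_trials_per_field_set Catch trials scheduled per field-on phase.
#' @param catch_duration Duration of the field switch-off window (s).
#' @param catch_error_gate Maximum tracking error at the crossing for a catch
#'   trial to be armed (m).
#' @param failed_turn_threshold Lap duration (s) at or above which a turn
#'   counts as failed rather than proper.
#'
#' @return An object of class `session_protocol`.
#' @export
session_protocol <- function(phases = default_phases(),
                             n_proper_turns = 30,
                             catch_trials_per_field_set = 6,
                             catch_duration = 0.5,
                             catch_error_gate = 0.02,
                             failed_turn_threshold = 12) {
  phases <- as_tibble(phases)
  if (!all(c("name", "field_on") %in% names(phases)))
    abort("`phases` needs columns `name` and `field_on`.")
  if (anyDuplicated(phases$name))
    abort("phase names must be unique.")
  if (n_proper_turns < 1) abort("`n_proper_turns` must be at least 1.")
  if (catch_duration <= 0) abort("`catch_duration` must be positive.")
  structure(
    list(phases = phases,
         n_proper_turns = as.integer(n_proper_turns),
         catch_trials_per_field_set = as.integer(catch_trials_per_field_set),
         catch_duration = catch_duration,
         catch_error_gate = catch_error_gate,
         failed_turn_threshold = failed_turn_threshold),
    class = "session_protocol"
  )
}

#' @rdname session_protocol
#' @export
default_phases <- function() {
  tibble(name = c("FA1", "FA2", "FF1", "FF2", "WO"),
         field_on = c(FALSE, FALSE, TRUE, TRUE, FALSE))
}

#' Read and write a structured configuration file
#'
#' The configuration file is flat YAML with three blocks, `task`, `subject`
#' and `protocol`, whose keys match the arguments of [task_config()],
#' [subject_params()] and [session_protocol()] (protocol phases as a list of
#' `name`/`field_on` pairs). All units are SI.
#'
#' @param path Path to a YAML configuration file.
#' @return `read_config()` returns a list with elements `task`, `subject`,
#'   `protocol`; `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  task <- do.call(task_config, raw$task %||% list())
  subject <- do.call(subject_params, raw$subject %||% list())
  praw <- raw$protocol %||% list()
  if (!is.null(praw$phases)) {
    praw$phases <- dplyr::bind_rows(lapply(praw$phases, as_tibble))
  }
  protocol <- do.call(session_protocol, praw)
  list(task = task, subject = subject, protocol = protocol)
}

#' @rdname read_config
#' @param task A [task_config()].
#' @param subject A [subject_params()].
#' @param protocol A [session_protocol()].
#' @export
write_config <- function(path, task = task_config(),
                         subject = subject_params(),
                         protocol = session_protocol()) {
  pr <- unclass(protocol)
  pr$phases <- purrr::pmap(protocol$phases, function(name, field_on)
    list(name = name, field_on = field_on))
  yaml::write_yaml(list(task = unclass(task), subject = unclass(subject),
                        protocol = pr), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  figure eight: A = %.3f m, B = %.3f m; lap period T = %g s\n",
              x$A, x$B, x$T_lap))
  cat(sprintf("  error gate D = %g m; curl field b = %g N s/m (%s velocity)\n",
              x$D, x$b, x$field_velocity_source))
  cat(sprintf("  sampling: %g Hz\n", x$fs))
  invisible(x)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>\n")
  cat(sprintf("  impedance: m = %g kg, K = %g N/m, B = %.1f N s/m\n",
              x$mass, x$stiffness, x$damping))
  cat(sprintf("  compensation gain = %g; replan %g Hz; plan noise sd %g m\n",
              x$compensation_gain, x$replan_rate, x$plan_noise_sd))
  cat(sprintf("  tau_adapt = %g laps, tau_washout = %g laps; seed %d\n",
              x$tau_adapt, x$tau_washout, x$seed))
  invisible(x)
}

#' @export
print.session_protocol <- function(x, ...) {
  cat("<session_protocol>\n")
  cat(sprintf("  phases: %s\n",
              paste0(x$phases$name, ifelse(x$phases$field_on, "*", ""),
                     collapse = " ")))
  cat(sprintf("  %d proper turns/phase; %d catch trials per field set (%g s)\n",
              x$n_proper_turns, x$catch_trials_per_field_set,
              x$catch_duration))
  invisible(x)
}
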