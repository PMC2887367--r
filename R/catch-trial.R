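#' Extract catch-trial records from a trajectory log
#'
#' Locates the unannounced field switch-off windows and reads, for each, the
#' lateral deviation at the last field-on sample (`LD_ini`), the lateral
#' deviation at the last sample of the window (`LD_fin`), and the
#' disturbance magnitude at onset `F_D = b * |v_hand(t0)|`. Windows shorter
#' than `min_duration` and windows whose tracking error at onset exceeds the
#' protocol's 2 cm gate are rejected: a large error at the crossing means
#' the quasi-static force balance the decomposition relies on does not hold.
#'
#' @param log A `trajectory_log` with `field_on` and `catch` annotations.
#' @param LD Optional precomputed lateral-deviation series for the log; if
#'   `NULL` it is computed from smoothed hand kinematics.
#' @param cfg A [task_config()]; defaults to the one attached to the log.
#' @param error_gate Maximum tracking error at onset (m).
#' @param min_duration Minimum usable switch-off duration (s).
#' @return A tibble of class `catch_trials`, one row per accepted window:
#'   `phase`, `lap`, `t0`, `tF`, `LD_ini`, `LD_fin`, `F_D`, `direction`.
#' @export
extract_catch_trials <- function(log, LD = NULL, cfg = attr(log, "cfg"),
                                 error_gate = 0.02, min_duration = 0.4) {
  if (is.null(cfg)) abort("no task_config attached to the log; pass `cfg`.")
  if (!"catch" %in% names(log)) abort("log has no `catch` column.")
  hand <- smooth_and_differentiate(log[, c("hand_x", "hand_y")], cfg$fs)
  if (is.null(LD))
    LD <- lateral_deviation(hand, cfg,
                            alpha = if ("alpha" %in% names(log)) log$alpha)
  runs <- run_bounds(log$catch == 1)
  if (!nrow(runs)) {
    return(empty_catch_table())
  }
  rows <- purrr::pmap(runs, function(from, to) {
    i0 <- from - 1L                       # last field-on sample
    if (i0 < 1 || log$field_on[i0] != 1) return(NULL)
    dur <- (to - from + 1L) / cfg$fs
    if (dur < min_duration) return(NULL)
    err0 <- sqrt((log$hand_x[i0] - log$target_x[i0])^2 +
                 (log$hand_y[i0] - log$target_y[i0])^2)
    if (err0 >= error_gate) return(NULL)
    vx <- hand$vx[i0]
    tibble(phase = log$phase[i0],
           lap = log$lap[i0],
           t0 = log$t[i0],
           tF = log$t[to],
           LD_ini = LD[i0],
           LD_fin = LD[to],
           F_D = cfg$b * hand$speed[i0],
           direction = if (vx >= 0) "rightward" else "leftward")
  })
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty_catch_table())
  class(out) <- c("catch_trials", class(out))
  out
}

empty_catch_table <- function() {
  out <- tibble(phase = character(), lap = integer(), t0 = numeric(),
                tF = numeric(), LD_ini = numeric(), LD_fin = numeric(),
                F_D = numeric(), direction = character())
  class(out) <- c("catch_trials", class(out))
  out
}

run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(from = starts[r$values], to = ends[r$values])
}

#' Decompose catch-trial deviations into stiffness and commanded force
#'
#' Under the quasi-static force balance in the direction normal to the path,
#' the field force at switch-off time is carried jointly by the commanded
#' force and the elastic restoring force of the arm:
#' \deqn{F_D = F_C + K \, LD_{ini}, \qquad 0 = F_C + K \, LD_{fin}}
#' (the second line holding at the end of the switch-off window, when the
#' field is absent but the command persists). Solving the pair gives
#' \deqn{K = \frac{F_D}{LD_{ini} - LD_{fin}}, \quad F_C = -K \, LD_{fin},
#'   \quad PAC = \frac{F_C}{F_D} = \frac{-LD_{fin}}{LD_{ini} - LD_{fin}}}
#' PAC, the proportion of active compensation, is the fraction of the
#' disturbance balanced by the voluntary command rather than by stiffness.
#' Trials with `LD_ini == LD_fin` are singular and flagged, not dropped
#' silently. Lateral deviations are already expressed in the common
#' rightward-positive frame, so leftward and rightward crossings decompose
#' identically.
#'
#' @param trials A `catch_trials` tibble (or any data frame with `LD_ini`,
#'   `LD_fin`, `F_D`).
#' @return The input with columns `K` (N/m), `F_C` (N), `PAC` and a logical
#'   `valid` flag appended; class `force_decomposition`.
#' @examples
#' decompose_forces(tibble::tibble(LD_ini = 0.004, LD_fin = -0.016, F_D = 12))
#' @export
decompose_forces <- function(trials) {
  dd <- trials$LD_ini - trials$LD_fin
  singular <- abs(dd) < 1e-12
  K <- ifelse(singular, NA_real_, trials$F_D / dd)
  out <- mutate(as_tibble(trials),
                K = K,
                F_C = -K * trials$LD_fin,
                PAC = ifelse(singular, NA_real_, -trials$LD_fin / dd),
                valid = !singular & K > 0)
  class(out) <- c("force_decomposition", class(out))
  out
}

#' Aggregate PAC, stiffness and commanded force over catch trials
#'
#' Arithmetic mean and standard error of the decomposed quantities over the
#' valid trials, overall and split by grouping columns (phase and crossing
#' direction when present). Invalid (singular or negative-stiffness) trials
#' are excluded and counted.
#'
#' @param decomps A `force_decomposition` tibble.
#' @param by Character vector of grouping columns present in `decomps`;
#'   the overall (ungrouped) summary is always included as group `"all"`.
#' @return A tibble with columns `group`, `n`, `n_excluded`, `PAC_mean`,
#'   `PAC_se`, `K_mean`, `K_se`, `F_C_mean`, `F_C_se`.
#' @export
aggregate_pac <- function(decomps, by = intersect(c("phase", "direction"),
                                                  names(decomps))) {
  ok <- dplyr::filter(decomps, .data$valid)
  if (nrow(ok) < 2)
    abort("need at least 2 valid catch-trial decompositions.")
  one <- function(d, label) {
    tibble(group = label, n = nrow(d),
           PAC_mean = mean(d$PAC), PAC_se = se(d$PAC),
           K_mean = mean(d$K), K_se = se(d$K),
           F_C_mean = mean(d$F_C), F_C_se = se(d$F_C))
  }
  res <- one(ok, "all")
  for (col in by) {
    parts <- split(ok, ok[[col]])
    parts <- parts[vapply(parts, nrow, 1L) >= 2]
    res <- bind_rows(res, bind_rows(unname(purrr::imap(parts, one))))
  }
  res$n_excluded <- sum(!decomps$valid)
  res
}

se <- function(x) sd(x) / sqrt(length(x))
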