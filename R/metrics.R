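#' Decompose the tracking error into longitudinal and normal components
#'
#' The instantaneous error vector `p_hand - p_target` is projected onto a
#' running frame attached to the target's direction of travel: the
#' longitudinal unit vector points along the target velocity (positive =
#' hand ahead of the target) and the normal unit vector is the longitudinal
#' one rotated 90 degrees clockwise, so positive normal error means the hand
#' is to the right of the travel direction. When the target is stalled
#' (speed below `speed_floor`, e.g. while it waits for the subject) the
#' frame freezes at its last valid orientation.
#'
#' @param hand,target `kinematic_series` (or data frames with `x`, `y` and,
#'   for the target, `vx`, `vy`) on the same time base.
#' @param speed_floor Target speed below which the frame is carried over (m/s).
#' @return A tibble with columns `e` (unsigned distance), `e_l`, `e_n` (m).
#' @examples
#' lap <- ideal_lap(task_config(), 800)
#' err <- error_decomposition(dplyr::mutate(lap, x = x + 0.01), lap)
#' @export
error_decomposition <- function(hand, target, speed_floor = 1e-4) {
  if (nrow(hand) != nrow(target))
    abort("hand and target series must have the same length.")
  ex <- hand$x - target$x
  ey <- hand$y - target$y
  sp <- sqrt(target$vx^2 + target$vy^2)
  ok <- sp > speed_floor
  if (!any(ok)) abort("target never moves: no frame can be defined.")
  ux <- target$vx / sp
  uy <- target$vy / sp
  # freeze the frame across stalled stretches (carry last valid sample)
  idx <- cummax(ifelse(ok, seq_along(ok), 0L))
  idx[idx == 0L] <- which(ok)[1]  # leading stall: use first valid frame
  ux <- ux[idx]; uy <- uy[idx]
  tibble(e = sqrt(ex^2 + ey^2),
         e_l = ex * ux + ey * uy,
         e_n = ex * uy - ey * ux)
}

#' Figural error between two paths
#'
#' A speed-insensitive shape distance: the symmetrized mean distance from
#' the points of each path to the polyline of the other,
#' \deqn{FE = \tfrac12\left[\mathrm{mean}_i d(A_i, B) +
#'   \mathrm{mean}_j d(B_j, A)\right]}
#' with point-to-polyline distances taken to segments, not vertices, so
#' resampling a path at a different rate changes the value only marginally.
#'
#' @param path_a,path_b Two-column matrices or data frames of x/y points (m).
#' @return The figural error (m).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)
#' figural_error(cbind(0.10 * cos(th), 0.10 * sin(th)),
#'               cbind(0.11 * cos(th), 0.11 * sin(th)))
#' @export
figural_error <- function(path_a, path_b) {
  A <- extract_xy(path_a); B <- extract_xy(path_b)
  if (nrow(A) < 2 || nrow(B) < 2)
    abort("paths need at least 2 points each.")
  (mean(points_to_polyline(A, B)) + mean(points_to_polyline(B, A))) / 2
}

# minimum distance from each row of P to the polyline with vertices V
points_to_polyline <- function(P, V) {
  ax <- V[-nrow(V), 1]; ay <- V[-nrow(V), 2]
  bx <- V[-1, 1]; by <- V[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  n_seg <- length(ax)
  out <- numeric(nrow(P))
  for (k in seq_len(nrow(P))) {
    px <- P[k, 1]; py <- P[k, 2]
    tt <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    qx <- ax + tt * dx; qy <- ay + tt * dy
    out[k] <- sqrt(min((px - qx)^2 + (py - qy)^2))
  }
  out
}

#' Correlation between speed and absolute curvature
#'
#' The speed-curvature coupling of a lap, reported as the magnitude of the
#' Pearson correlation between the speed profile and the absolute curvature
#' profile. Errorless tracking of the figure eight yields 0.91; human
#' performance is lower and drops further under the force field as the
#' trajectory becomes more segmented.
#'
#' @param hand A `kinematic_series`.
#' @param speed_floor Passed to [curvature()].
#' @return `|corr|` in `[0, 1]`, or `NA_real_` when either profile is
#'   constant over the valid samples.
#' @export
speed_curvature_correlation <- function(hand, speed_floor = 1e-3) {
  k <- if ("curvature" %in% names(hand)) hand$curvature
       else curvature(hand, speed_floor)
  sp <- if ("speed" %in% names(hand)) hand$speed
        else sqrt(hand$vx^2 + hand$vy^2)
  ok <- is.finite(k) & is.finite(sp)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(sp[ok]) == 0 || sd(abs(k[ok])) == 0) return(NA_real_)
  abs(cor(sp[ok], abs(k[ok])))
}

#' Signed lateral deviation from the nominal path
#'
#' The minimum instantaneous distance from the hand to the ideal
#' eight-shaped path, signed positive when the hand lies to the right of the
#' local direction of travel. The path is densely sampled in the phase
#' angle and the hand is projected onto the resulting polyline. Because the
#' figure crosses itself at the origin, a global nearest-point projection is
#' ambiguous near the crossing; passing the target's concurrent phase angle
#' in `alpha` restricts the search to the branch the target is actually on.
#'
#' @param hand A `kinematic_series` or data frame with hand x/y columns.
#' @param cfg A [task_config()].
#' @param alpha Optional numeric vector (same length as `hand`) of target
#'   phase angles used to disambiguate the branch; the projection is then
#'   restricted to path points within a quarter turn of `alpha`.
#' @param n_path Number of path samples per lap used for the projection.
#' @return Signed lateral deviation series (m), positive rightward.
#' @examples
#' lap <- ideal_lap(task_config(), 400)
#' max(abs(lateral_deviation(lap, task_config(), alpha = lap$alpha)))
#' @export
lateral_deviation <- function(hand, cfg = task_config(), alpha = NULL,
                              n_path = 720) {
  H <- extract_xy(hand)
  hx <- H[, 1]; hy <- H[, 2]
  n <- length(hx)
  a_grid <- seq(0, 2 * pi, length.out = n_path + 1)[seq_len(n_path)]
  p <- lissajous_point(a_grid, cfg)
  px <- p$x; py <- p$y
  tx <- p$dx_dalpha; ty <- p$dy_dalpha
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl

  # nearest path vertex, swept as vectorized passes over grid offsets;
  # with target phase angles the search is a quarter turn around the
  # target's own branch, which disambiguates the central crossing
  if (is.null(alpha)) {
    j0 <- rep(1L, n)
    offsets <- 0:(n_path - 1)
  } else {
    j0 <- (round(alpha / (2 * pi) * n_path) %% n_path) + 1L
    qw <- ceiling(n_path / 4)
    offsets <- -qw:qw
  }
  best_d2 <- rep(Inf, n)
  best_j <- j0
  for (o in offsets) {
    idx <- ((j0 - 1L + o) %% n_path) + 1L
    d2 <- (hx - px[idx])^2 + (hy - py[idx])^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_j[hit] <- idx[hit]
  }
  # refine: project onto the two segments adjacent to the best vertex
  seg_dist <- function(j_a, j_b) {
    ax <- px[j_a]; ay <- py[j_a]
    dx <- px[j_b] - ax; dy <- py[j_b] - ay
    len2 <- dx^2 + dy^2
    tt <- pmin(pmax(((hx - ax) * dx + (hy - ay) * dy) / len2, 0), 1)
    qx <- ax + tt * dx; qy <- ay + tt * dy
    list(d2 = (hx - qx)^2 + (hy - qy)^2, qx = qx, qy = qy)
  }
  j_prev <- ((best_j - 2L) %% n_path) + 1L
  j_next <- (best_j %% n_path) + 1L
  s1 <- seg_dist(j_prev, best_j)
  s2 <- seg_dist(best_j, j_next)
  use1 <- s1$d2 <= s2$d2
  qx <- ifelse(use1, s1$qx, s2$qx)
  qy <- ifelse(use1, s1$qy, s2$qy)
  rx <- hx - qx; ry <- hy - qy
  # rightward of travel = along the clockwise-rotated tangent (ty, -tx)
  s <- sign(rx * ty[best_j] - ry * tx[best_j])
  s[s == 0] <- 1
  s * sqrt(rx^2 + ry^2)
}

#' Correlation between movement speed and lateral deviation
#'
#' The force-movement correlation (FMC): since the disturbance force is
#' proportional to speed, any uncompensated component shows up as a lateral
#' deviation that co-varies with the speed profile. A small FMC indicates
#' that the commanded force tracks the speed-dependent disturbance
#' efficiently, leaving the lateral error decoupled from speed.
#'
#' @param speed,LD Equal-length numeric lap series.
#' @return `|corr|` in `[0, 1]`, or `NA_real_` for constant input.
#' @export
force_movement_correlation <- function(speed, LD) {
  if (length(speed) != length(LD)) abort("series lengths differ.")
  ok <- is.finite(speed) & is.finite(LD)
  if (sum(ok) < 3 || sd(speed[ok]) == 0 || sd(LD[ok]) == 0) return(NA_real_)
  abs(cor(speed[ok], LD[ok]))
}

#' Per-lap tracking and force-control indicators
#'
#' Computes the full per-lap indicator table from an annotated trajectory
#' log: lap duration (DUR) with the proper-turn flag, the tracking error and
#' its longitudinal/normal decomposition (delta, delta_l, delta_n), figural
#' error of the hand path against the target path (FE), submovement count
#' (NP), speed-|curvature| correlation (CC), lateral-deviation statistics
#' and the force-movement correlation (FMC). Hand and target positions are
#' smoothed and differentiated once over the whole log; the first and last
#' filter half-window of each lap is excluded from the averages.
#'
#' @param log A `trajectory_log` (from [simulate_session()] or
#'   [read_trajectory_log()]).
#' @param cfg A [task_config()]; defaults to the one attached to the log.
#' @return A tibble of class `lap_metrics`, one row per lap, with columns
#'   `phase`, `lap`, `DUR`, `delta`, `delta_l`, `delta_n`, `FE`, `NP`, `CC`,
#'   `LD_mean`, `LD_sd`, `FMC`, `proper`.
#' @export
lap_table <- function(log, cfg = attr(log, "cfg")) {
  if (is.null(cfg)) abort("no task_config attached to the log; pass `cfg`.")
  if (!all(c("lap", "phase") %in% names(log)))
    abort("log is missing lap/phase annotations.")
  fs <- cfg$fs
  hand <- smooth_and_differentiate(log[, c("hand_x", "hand_y")], fs)
  target <- smooth_and_differentiate(log[, c("target_x", "target_y")], fs)
  hand$curvature <- curvature(hand, cfg$speed_floor)
  err <- error_decomposition(hand, target)
  LD <- lateral_deviation(hand, cfg,
                          alpha = if ("alpha" %in% names(log)) log$alpha)
  half <- (attr(hand, "window") - 1) / 2
  threshold <- attr(log, "protocol")$failed_turn_threshold %||% 12

  laps <- split(seq_len(nrow(log)), log$lap)
  rows <- purrr::map(laps, function(ix) {
    dur <- (length(ix)) / fs
    core <- ix[ix >= min(ix) + half & ix <= max(ix) - half]
    # catch-trial switch-off windows obey a different force balance and are
    # analysed separately; keep them out of the ordinary lap indicators
    if ("catch" %in% names(log)) core <- core[log$catch[core] == 0]
    if (length(core) < 3) core <- ix
    tibble(
      phase = log$phase[ix[1]],
      lap = log$lap[ix[1]],
      DUR = dur,
      delta = mean(err$e[core]),
      delta_l = mean(err$e_l[core]),
      delta_n = mean(err$e_n[core]),
      FE = figural_error(cbind(hand$x[core], hand$y[core]),
                         cbind(target$x[core], target$y[core])),
      # a lap is a closed circuit: circular counting avoids double-counting
      # the speed peak split across the lap boundary at the crossing
      NP = segment_submovements(hand$speed[core], fs,
                                cfg$min_prominence_frac,
                                circular = TRUE)$count,
      CC = speed_curvature_correlation(hand[core, ]),
      LD_mean = mean(LD[core]),
      LD_sd = sd(LD[core]),
      FMC = force_movement_correlation(hand$speed[core], LD[core]),
      proper = dur < threshold
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("lap_metrics", class(out))
  attr(out, "cfg") <- cfg
  out
}

#' Phase-level summary of lap metrics
#'
#' Aggregates a [lap_table()] to phase means with standard deviation and
#' standard error per indicator, the basic summary the per-lap indicators
#' are reported with.
#'
#' @param laps A `lap_metrics` tibble.
#' @param proper_only Use proper turns only (default `TRUE`).
#' @return A long tibble with columns `phase`, `indicator`, `mean`, `sd`,
#'   `se`, `n`.
#' @export
phase_summary <- function(laps, proper_only = TRUE) {
  d <- if (proper_only) dplyr::filter(laps, .data$proper) else laps
  d %>%
    select(-"proper") %>%
    tidyr::pivot_longer(-c("phase", "lap"), names_to = "indicator") %>%
    group_by(.data$phase, .data$indicator) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              se = sd(.data$value, na.rm = TRUE) /
                sqrt(sum(is.finite(.data$value))),
              n = sum(is.finite(.data$value)),
              .groups = "drop")
}
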