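#' Smooth a raw position log and estimate its derivatives
#'
#' Positions are smoothed with a 6th-order Savitzky-Golay filter with a
#' 170 ms window (17 samples at 100 Hz, roughly an 11 Hz cut-off), and the
#' same local polynomial fit supplies the first and second time derivatives.
#' Edge samples come from the filter's polynomial extrapolation; downstream
#' per-lap metrics exclude the first and last half-window.
#'
#' @param raw_positions A data frame (or matrix) with two numeric columns,
#'   x and y positions in meters, or a data frame containing columns
#'   `x`/`y` (or `hand_x`/`hand_y`).
#' @param fs Sampling rate (Hz).
#' @param window Filter window length in samples (odd; default 17).
#' @param order Polynomial order of the filter (default 6).
#' @return A tibble of class `kinematic_series` with columns `t`, `x`, `y`,
#'   `vx`, `vy`, `ax`, `ay`, `speed`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' smooth_and_differentiate(data.frame(x = t^2, y = 0 * t), fs = 100)
#' @export
smooth_and_differentiate <- function(raw_positions, fs, window = 17,
                                     order = 6) {
  xy <- extract_xy(raw_positions)
  n <- nrow(xy)
  if (n < window)
    abort(sprintf("series too short: %d samples, window needs %d.", n, window))
  if (window %% 2 == 0) abort("`window` must be odd.")
  sg <- function(v, m) signal::sgolayfilt(v, p = order, n = window, m = m,
                                          ts = 1 / fs)
  out <- tibble(
    t = (seq_len(n) - 1) / fs,
    x = sg(xy[, 1], 0), y = sg(xy[, 2], 0),
    vx = sg(xy[, 1], 1), vy = sg(xy[, 2], 1),
    ax = sg(xy[, 1], 2), ay = sg(xy[, 2], 2)
  )
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  attr(out, "fs") <- fs
  attr(out, "window") <- window
  class(out) <- c("kinematic_series", class(out))
  out
}

extract_xy <- function(d) {
  if (is.matrix(d)) return(d[, 1:2, drop = FALSE])
  d <- as.data.frame(d)
  for (pair in list(c("x", "y"), c("hand_x", "hand_y"),
                    c("target_x", "target_y"))) {
    if (all(pair %in% names(d))) return(as.matrix(d[, pair]))
  }
  if (ncol(d) >= 2 && all(vapply(d[1:2], is.numeric, TRUE)))
    return(as.matrix(d[, 1:2]))
  abort("cannot find an x/y position pair in the input.")
}

#' Signed curvature of a planar kinematic series
#'
#' Computes the signed curvature
#' \deqn{\kappa = (\dot{x}\ddot{y} - \dot{y}\ddot{x}) / |v|^3}
#' (positive for counter-clockwise turning in the x-right, y-up frame).
#' Samples with speed below the configured floor are set to `NA`, since the
#' ratio is numerically meaningless at rest.
#'
#' @param series A `kinematic_series` from [smooth_and_differentiate()], or
#'   any data frame with `vx`, `vy`, `ax`, `ay` columns.
#' @param speed_floor Validity floor on speed (m/s).
#' @return Numeric vector of signed curvature (1/m) with `NA` at invalid
#'   samples.
#' @export
curvature <- function(series, speed_floor = 1e-3) {
  sp <- sqrt(series$vx^2 + series$vy^2)
  if (all(sp <= speed_floor)) abort("all samples are below the speed floor.")
  k <- (series$vx * series$ay - series$vy * series$ax) / sp^3
  k[sp <= speed_floor] <- NA_real_
  k
}

#' Segment a speed profile into submovements
#'
#' Submovements are the speed pulses delimited by local minima of the speed
#' profile; each pulse carries exactly one speed peak, and the pulse count
#' per lap (NP) indexes the intermittency of the tracking controller. Minima
#' are accepted as boundaries only if their prominence (depth relative to
#' the lower of the two enclosing maxima) reaches
#' `min_prominence_frac * max(speed)`, which keeps the count finite under
#' measurement noise. For a closed lap, set `circular = TRUE` so the
#' wrap-around peak at the lap boundary is counted once.
#'
#' @param speed Non-negative numeric speed series (m/s).
#' @param fs Sampling rate (Hz); recorded on the output.
#' @param min_prominence_frac Prominence floor as a fraction of `max(speed)`.
#' @param circular Treat the series as one closed period.
#' @return A list of class `submovement_set` with elements `boundaries`
#'   (indices of accepted speed minima), `peaks` (index of the speed maximum
#'   of each segment) and `count` (NP).
#' @examples
#' lap <- ideal_lap(task_config(), 800)
#' segment_submovements(lap$speed, 100, circular = TRUE)$count
#' @export
segment_submovements <- function(speed, fs, min_prominence_frac = 0.02,
                                 circular = FALSE) {
  if (!length(speed)) abort("empty speed series.")
  if (any(speed < 0)) abort("speed must be non-negative.")
  n <- length(speed)
  floor_val <- min_prominence_frac * max(speed)
  mins <- local_minima(speed)
  if (length(mins)) {
    prom <- vapply(mins, function(i) minimum_prominence(speed, i, circular),
                   numeric(1))
    mins <- mins[prom >= floor_val]
  }
  if (circular) {
    if (length(mins) == 0) {
      segs <- list(seq_len(n))
    } else {
      bnd <- mins
      segs <- vector("list", length(bnd))
      for (j in seq_along(bnd)) {
        from <- bnd[j]
        to <- if (j < length(bnd)) bnd[j + 1] else bnd[1] + n
        segs[[j]] <- ((seq(from, to) - 1) %% n) + 1
      }
    }
  } else {
    bnd <- c(1L, mins, n)
    bnd <- unique(bnd)
    segs <- purrr::map2(bnd[-length(bnd)], bnd[-1], seq)
  }
  peaks <- vapply(segs, function(ix) ix[which.max(speed[ix])], numeric(1))
  structure(list(boundaries = mins, peaks = as.integer(peaks),
                 count = length(segs), fs = fs),
            class = "submovement_set")
}

# interior strict-ish local minima; plateaus yield their first index
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] < x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] > x[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# prominence of a speed minimum: lower of the two barrier heights between it
# and the nearest deeper minimum (or series end), minus the minimum's value
minimum_prominence <- function(x, i, circular = FALSE) {
  n <- length(x)
  if (circular) x <- c(x, x, x)  # unroll one period each side
  ctr <- if (circular) i + n else i
  lo <- x[ctr]
  left_max <- -Inf
  j <- ctr - 1L
  while (j >= 1L) {
    if (x[j] < lo) break
    left_max <- max(left_max, x[j])
    j <- j - 1L
  }
  right_max <- -Inf
  j <- ctr + 1L
  while (j <= length(x)) {
    if (x[j] < lo) break
    right_max <- max(right_max, x[j])
    j <- j + 1L
  }
  min(left_max, right_max) - lo
}

#' Dominant frequency of a speed profile
#'
#' Estimates the intermittency frequency as the largest peak of a
#' Welch-averaged power spectrum of the mean-removed speed profile above
#' `f_min` (0.5 Hz by default, to skip the lap fundamental and its low
#' harmonics). The spectrum is averaged over Hann-windowed segments of
#' `seg_seconds` with 50% overlap, which flattens the noise floor enough
#' that a genuine periodicity stands out; if no averaged bin above `f_min`
#' exceeds three times the median power in that band, no meaningful
#' periodicity exists and `NA` is returned.
#'
#' @param speed Numeric speed series (m/s).
#' @param fs Sampling rate (Hz).
#' @param f_min Lower frequency bound (Hz).
#' @param seg_seconds Welch segment length (s); also sets the frequency
#'   resolution `1/seg_seconds`.
#' @return The peak frequency (Hz), or `NA_real_` when no peak stands out.
#' @export
dominant_frequency <- function(speed, fs, f_min = 0.5, seg_seconds = 5) {
  n <- length(speed)
  if (n < 4 * fs) abort("need at least 4 s of data.")
  x <- speed - mean(speed)
  L <- min(n, round(seg_seconds * fs))
  hop <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  pw <- rowMeans(vapply(starts, function(s0) {
    seg <- x[s0:(s0 + L - 1L)]
    Mod(fft((seg - mean(seg)) * w))^2
  }, numeric(L)))
  freqs <- (seq_len(L) - 1) * fs / L
  keep <- freqs > f_min & freqs <= fs / 2
  pw <- pw[keep]; freqs <- freqs[keep]
  if (max(pw) < 3 * stats::median(pw)) return(NA_real_)
  freqs[which.max(pw)]
}
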