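#' Fit an exponential learning curve to per-lap tracking error
#'
#' Fits \deqn{\delta(k) = A_0 \exp(-k / \tau) + A_1} by nonlinear least
#' squares to a per-lap error series, where `k` counts laps since the start
#' of the phase, `A_1` is the asymptotic error, `A_0` the decaying amplitude
#' and `tau` the learning time constant in laps. The fit is multi-started
#' from `tau` in `{2, 5, 15}` laps with `A_1` initialized at the mean of the
#' last five laps and `A_0` at the first lap's excess over it; the start
#' with the lowest residual sum of squares wins. A series with no resolvable
#' decay (all starts failing, or a vanishing fitted amplitude) is returned
#' flagged rather than dropped.
#'
#' @param delta_per_lap Positive per-lap error values (m).
#' @param lap_index Lap counter; defaults to `0, 1, ...` over the series.
#' @param tau_starts Multi-start values for `tau` (laps).
#' @return An object of class `learning_fit` with elements `A0`, `A1`,
#'   `tau`, `r2`, `n_laps`, `converged`, `fitted`, `data`.
#' @examples
#' k <- 0:59
#' fit <- fit_learning_curve(0.03 * exp(-k / 9.4) + 0.015, k)
#' fit$tau
#' @export
fit_learning_curve <- function(delta_per_lap, lap_index = NULL,
                               tau_starts = c(2, 5, 15)) {
  y <- as.numeric(delta_per_lap)
  if (is.null(lap_index)) lap_index <- seq_along(y) - 1
  k <- as.numeric(lap_index)
  ok <- is.finite(y) & is.finite(k)
  y <- y[ok]; k <- k[ok]
  if (length(y) < 5) abort("need at least 5 laps to fit a learning curve.")
  if (any(y < 0)) abort("per-lap errors must be non-negative.")

  A1_0 <- mean(tail(y[order(k)], 5))
  A0_0 <- max(y[which.min(k)] - A1_0, 1e-6)
  d <- data.frame(k = k, y = y)
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A0 * exp(-k / tau) + A1, data = d,
                        start = list(A0 = A0_0, A1 = A1_0, tau = tau0),
                        lower = c(A0 = 0, A1 = 0, tau = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    out <- list(A0 = NA_real_, A1 = mean(y), tau = NA_real_, r2 = NA_real_,
                n_laps = length(y), converged = FALSE,
                fitted = rep(mean(y), length(y)),
                data = tibble(lap = k, delta = y))
    class(out) <- "learning_fit"
    return(out)
  }

  cf <- coef(best$fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  # a fitted amplitude indistinguishable from zero leaves tau unidentified
  identified <- cf[["A0"]] > 1e-8 * max(mean(y), 1e-12)
  out <- list(A0 = unname(cf["A0"]), A1 = unname(cf["A1"]),
              tau = if (identified) unname(cf["tau"]) else NA_real_,
              r2 = r2, n_laps = length(y),
              converged = identified,
              fitted = as.numeric(predict(best$fit)),
              data = tibble(lap = k, delta = y))
  class(out) <- "learning_fit"
  out
}

#' @export
print.learning_fit <- function(x, ...) {
  cat("<learning_fit>\n")
  if (x$converged) {
    cat(sprintf("  delta(k) = %.4f * exp(-k / %.2f) + %.4f  [m, laps]\n",
                x$A0, x$tau, x$A1))
    cat(sprintf("  r^2 = %.3f over %d laps\n", x$r2, x$n_laps))
  } else {
    cat(sprintf("  no resolvable decay over %d laps (mean %.4f m)\n",
                x$n_laps, x$A1))
  }
  invisible(x)
}

#' @describeIn fit_learning_curve One row per parameter, broom-style.
#' @param x A `learning_fit`.
#' @param ... Unused.
#' @method tidy learning_fit
#' @export
tidy.learning_fit <- function(x, ...) {
  tibble(term = c("A0", "A1", "tau"),
         estimate = c(x$A0, x$A1, x$tau))
}

#' @describeIn fit_learning_curve One-row fit summary, broom-style.
#' @method glance learning_fit
#' @export
glance.learning_fit <- function(x, ...) {
  tibble(r.squared = x$r2, n_laps = x$n_laps, converged = x$converged,
         tau = x$tau, A0 = x$A0, A1 = x$A1)
}

#' @describeIn fit_learning_curve Learning-curve plot: per-lap error and the
#'   fitted exponential.
#' @param object A `learning_fit`.
#' @method autoplot learning_fit
#' @export
autoplot.learning_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lap)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$delta), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "lap", y = "tracking error (m)",
                  title = if (object$converged)
                    sprintf("tau = %.2f laps, r² = %.2f",
                            object$tau, object$r2)
                  else "no resolvable decay") +
    ggplot2::theme_minimal()
}
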