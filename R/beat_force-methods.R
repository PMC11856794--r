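# S3 methods for the "beat_force" fit object.

#' @export
print.beat_force <- function(x, ...) {
  cat("Beating-force reconstruction (Euler-Bernoulli cantilever inversion)\n")
  cat(sprintf("  probe: L = %.4g mm, d = %.4g mm, EI = %.4g N m^2\n",
              x$spec$length * 1e3, x$spec$diameter * 1e3, x$spec$EI))
  cat(sprintf("  analysis window: %.4g s (%d samples at %.4g Hz)\n",
              x$decomposition$T_rec, x$decomposition$n_used, x$trace$fs))
  cat(sprintf("  harmonics retained: %d (dropped energy %.3g)\n",
              nrow(x$force_harmonics), x$decomposition$dropped_energy))
  cat(sprintf("  static term: %.4g uN; peak force: %.4g uN\n",
              x$static_term * 1e6, max(x$force$values) * 1e6))
  cat(sprintf("  dynamic correction vs quasi-static: %.3g%%\n",
              100 * x$dynamic_correction))
  invisible(x)
}

#' Beat kinetics summary of a force reconstruction
#'
#' Segments the reconstructed force into beats and reports per-beat twitch
#' kinetics and their mean/SD across beats.
#'
#' @param object A \code{\link{beat_force}} fit.
#' @param min_prominence,refractory Passed to \code{\link{segment_beats}}.
#' @param baseline_subtract Passed to \code{\link{beat_parameters}}.
#' @param ... Unused.
#' @return A list of class \code{"summary.beat_force"} with \code{beats}
#'   (per-beat \code{beat_metrics}) and \code{table}
#'   (\code{\link{beat_summary}}).
#' @export
summary.beat_force <- function(object, min_prominence = 0.5,
                               refractory = 0.2, baseline_subtract = TRUE,
                               ...) {
  beats <- beat_metrics(object$force, min_prominence, refractory,
                        baseline_subtract)
  structure(list(beats = beats,
                 table = if (nrow(beats)) beat_summary(beats) else NULL,
                 fit = object),
            class = "summary.beat_force")
}

#' @export
print.summary.beat_force <- function(x, ...) {
  print(x$fit)
  if (is.null(x$table)) {
    cat("  no usable beats found\n")
    return(invisible(x))
  }
  cat(sprintf("\nBeat kinetics over %d beat(s) (mean +/- SD):\n",
              nrow(x$beats)))
  unit <- c(B_m = "uN", T_1 = "s", T_m = "s", T_2 = "s", F_c = "uN/s",
            F_r = "uN/s", FI = "uN s", F_c_norm = "1/s", F_r_norm = "1/s",
            FI_norm = "s")
  scale <- c(B_m = 1e6, T_1 = 1, T_m = 1, T_2 = 1, F_c = 1e6, F_r = 1e6,
             FI = 1e6, F_c_norm = 1, F_r_norm = 1, FI_norm = 1)
  for (i in seq_len(nrow(x$table))) {
    p <- x$table$parameter[i]
    cat(sprintf("  %-9s %10.4g +/- %-8.3g %s\n", p,
                x$table$mean[i] * scale[[p]], x$table$sd[i] * scale[[p]],
                unit[[p]]))
  }
  invisible(x)
}

#' @export
coef.beat_force <- function(object, ...) {
  beats <- beat_metrics(object$force)
  as.matrix(beats[, c("B_m", "T_1", "T_m", "T_2", "F_c", "F_r", "FI",
                      "F_c_norm", "F_r_norm", "FI_norm")])
}

#' @export
fitted.beat_force <- function(object, ...) object$force$values

#' Residual displacement of a beat-force fit
#'
#' The part of the measured displacement not carried by the retained
#' harmonics (truncation residue plus measurement noise), on the analysis
#' window.
#'
#' @param object A \code{\link{beat_force}} fit.
#' @param ... Unused.
#' @return Numeric vector in metres.
#' @export
residuals.beat_force <- function(object, ...) {
  n <- object$decomposition$n_used
  object$trace$values[seq_len(n)] -
    spectral_reconstruct(object$decomposition, object$trace$times[seq_len(n)])
}

#' Evaluate the reconstructed force model at arbitrary times
#'
#' Uses the fitted harmonic force model (periodic continuation of the
#' analysis window).
#'
#' @param object A \code{\link{beat_force}} fit.
#' @param times Times in seconds (default: the analysis grid).
#' @param ... Unused.
#' @return Force in newtons.
#' @export
predict.beat_force <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$force$values)
  h <- object$force_harmonics
  tt <- times - object$decomposition$t0
  out <- rep(object$static_term, length(times))
  for (i in seq_len(nrow(h)))
    out <- out + h$amplitude_N[i] * cos(h$omega[i] * tt + h$phi[i])
  out
}

#' Plot a beat-force reconstruction
#'
#' Two stacked panels: the measured tip displacement (with the truncated
#' harmonic representation overlaid) and the reconstructed beating force
#' with its quasi-static baseline.
#'
#' @param x A \code{\link{beat_force}} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.beat_force <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4.5, 1.5, 1))
  on.exit(graphics::par(op))
  n <- x$decomposition$n_used
  t <- x$trace$times[seq_len(n)]
  graphics::plot(t, x$trace$values[seq_len(n)] * 1e6, type = "l",
                 col = "grey50", xlab = "time (s)",
                 ylab = "tip displacement (um)", ...)
  graphics::lines(t, spectral_reconstruct(x$decomposition, t) * 1e6,
                  col = "black")
  graphics::legend("topright", c("measured", "harmonic model"),
                   col = c("grey50", "black"), lty = 1, bty = "n",
                   cex = 0.8)
  graphics::plot(x$force$times, x$force$values * 1e6, type = "l",
                 xlab = "time (s)", ylab = "beating force (uN)", ...)
  graphics::lines(x$force$times, x$quasistatic * 1e6, col = "grey60",
                  lty = 2)
  graphics::legend("topright", c("reconstructed", "quasi-static"),
                   col = c("black", "grey60"), lty = c(1, 2), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Simulate displacement traces from a fitted model
#'
#' Draws synthetic measurement replicates: the fitted harmonic
#' displacement model evaluated on the analysis grid, pixel-quantized and
#' perturbed with Gaussian tracking noise.
#'
#' @param object A \code{\link{beat_force}} fit.
#' @param nsim Number of replicates.
#' @param seed RNG seed.
#' @param sigma_px,pixel_scale Noise model; \code{pixel_scale} defaults to
#'   the trace's recorded scale or 1e-6 m/px.
#' @param ... Unused.
#' @return A list of \code{\link{displacement_trace}} objects.
#' @export
simulate.beat_force <- function(object, nsim = 1, seed = NULL,
                                sigma_px = 0.5, pixel_scale = NULL, ...) {
  if (is.null(pixel_scale))
    pixel_scale <- if (!is.null(object$trace$pixel_scale))
      object$trace$pixel_scale else 1e-6
  if (is.null(seed)) seed <- 1L
  n <- object$decomposition$n_used
  t <- object$trace$times[seq_len(n)]
  base <- displacement_trace(t, spectral_reconstruct(object$decomposition, t))
  lapply(seq_len(nsim), function(i)
    add_measurement_noise(base, pixel_scale, sigma_px, seed = seed + i - 1L))
}
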