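# Parametric twitch-force generator.  One pulse per beat period:
#   g(u) = (1 - exp(-u/rise_tau))^p * exp(-u/decay_tau),  u = time in period,
# scaled so the peak equals `amplitude` and the baseline is 0.  The two time
# constants control the rise and relaxation independently, mirroring the
# T_1 / T_m / T_2 structure of a cardiac twitch; p >= 2 gives a smooth
# (zero-slope) onset and a rapidly decaying spectrum.

#' Twitch waveform parameters
#'
#' The atrial and ventricular presets are synthetic defaults chosen only to
#' reproduce the qualitative subtype ordering (atrial twitches are faster:
#' larger normalized contraction/relaxation velocities, smaller normalized
#' force-time integral); they are not measured values.
#'
#' @param preset \code{"atrial"} (rise 0.04 s, decay 0.06 s),
#'   \code{"ventricular"} (rise 0.10 s, decay 0.18 s) or \code{"custom"}.
#' @param amplitude Peak force in newtons (default 10 uN).
#' @param beat_rate Beats per second (default 1 Hz).
#' @param rise_tau,decay_tau Time constants in seconds (required for
#'   \code{"custom"}, overridable for presets).
#' @param shape Rise-saturation exponent p (default 2).
#' @return A list of class \code{"twitch_params"}.
#' @export
twitch_params <- function(preset = c("ventricular", "atrial", "custom"),
                          amplitude = 10e-6, beat_rate = 1,
                          rise_tau = NULL, decay_tau = NULL, shape = 2) {
  preset <- match.arg(preset)
  if (preset == "atrial") {
    if (is.null(rise_tau)) rise_tau <- 0.04
    if (is.null(decay_tau)) decay_tau <- 0.06
  } else if (preset == "ventricular") {
    if (is.null(rise_tau)) rise_tau <- 0.10
    if (is.null(decay_tau)) decay_tau <- 0.18
  } else if (is.null(rise_tau) || is.null(decay_tau)) {
    stop("custom twitch needs 'rise_tau' and 'decay_tau'", call. = FALSE)
  }
  if (amplitude <= 0) stop("'amplitude' must be positive", call. = FALSE)
  if (beat_rate <= 0) stop("'beat_rate' must be positive", call. = FALSE)
  if (rise_tau <= 0 || decay_tau <= 0 || shape < 1)
    stop("time constants must be positive and 'shape' >= 1", call. = FALSE)
  period <- 1 / beat_rate
  t_peak <- rise_tau * log(1 + shape * decay_tau / rise_tau)
  if (rise_tau >= period || t_peak + 4 * decay_tau > period)
    stop(sprintf(
      "twitch does not fit in the %.3g s beat period (peak at %.3g s + decay window %.3g s)",
      period, t_peak, 4 * decay_tau), call. = FALSE)
  structure(list(preset = preset, amplitude = amplitude,
                 beat_rate = beat_rate, rise_tau = rise_tau,
                 decay_tau = decay_tau, shape = shape, t_peak = t_peak),
            class = "twitch_params")
}

# unit-peak single-pulse shape on in-period time u >= 0
.twitch_pulse <- function(u, p) {
  g <- (1 - exp(-u / p$rise_tau))^p$shape * exp(-u / p$decay_tau)
  gmax <- (1 - exp(-p$t_peak / p$rise_tau))^p$shape *
    exp(-p$t_peak / p$decay_tau)
  g / gmax
}

#' Generate a periodic twitch-force train
#'
#' @param params A \code{\link{twitch_params}} object.
#' @param times Evaluation times in seconds (uniform grid for the returned
#'   \code{\link{force_trace}}).
#' @param ramp_beats Number of initial beats multiplied by a smooth cosine
#'   ramp (0 = none). Ramping avoids exciting free vibration when the
#'   train drives the forward beam simulator from rest.
#' @return A \code{\link{force_trace}} with attribute \code{"truth"}: the
#'   generator-truth \code{\link{beat_parameters}} of a single pulse
#'   evaluated on a dense grid (20 kHz), with baseline 0.
#' @export
twitch_force <- function(params, times, ramp_beats = 0) {
  stopifnot(inherits(params, "twitch_params"))
  period <- 1 / params$beat_rate
  u <- (times - times[1]) %% period
  v <- params$amplitude * .twitch_pulse(u, params)
  if (ramp_beats > 0) {
    tt <- times - times[1]
    ramp <- ifelse(tt < ramp_beats * period,
                   0.5 * (1 - cos(pi * tt / (ramp_beats * period))), 1)
    v <- v * ramp
  }
  out <- force_trace(times, v,
                     provenance = c(list(source = "twitch_force"),
                                    unclass(params)))
  attr(out, "truth") <- twitch_truth(params)
  out
}

#' Generator-truth kinetics of a single twitch pulse
#'
#' Evaluates one pulse on a dense 20 kHz grid and applies the same
#' 20-percent-threshold definitions as \code{\link{beat_parameters}},
#' giving the reference metrics that the measurement pipeline should
#' recover.
#'
#' @param params A \code{\link{twitch_params}} object.
#' @return A one-row \code{beat_metrics} data frame.
#' @export
twitch_truth <- function(params) {
  stopifnot(inherits(params, "twitch_params"))
  period <- 1 / params$beat_rate
  tt <- seq(0, period, by = 5e-5)
  ft <- force_trace(tt, params$amplitude * .twitch_pulse(tt, params),
                    provenance = list(source = "twitch_truth"))
  beat_parameters(ft, c(1L, length(tt)), baseline_subtract = FALSE)
}

#' Quantize and perturb a trace like a 60-fps camera measurement
#'
#' Models the video measurement chain: displacement is quantized to the
#' pixel grid, then perturbed by zero-mean Gaussian tracking noise of
#' \code{sigma_px} pixels. The camera gives no noise specification, so the
#' defaults are configurable synthetic values.
#'
#' @param trace A \code{\link{displacement_trace}}.
#' @param pixel_scale Metres per pixel (> 0).
#' @param sigma_px Tracking-noise SD in pixels (default 0.5).
#' @param seed RNG seed, recorded in the output's \code{noise} attribute.
#' @return A \code{\link{displacement_trace}} with attribute \code{"noise"}
#'   recording \code{pixel_scale}, \code{sigma_px} and \code{seed}.
#' @export
add_measurement_noise <- function(trace, pixel_scale, sigma_px = 0.5, seed) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (pixel_scale <= 0) stop("'pixel_scale' must be positive", call. = FALSE)
  set.seed(seed)
  v <- round(trace$values / pixel_scale) * pixel_scale
  if (sigma_px > 0)
    v <- v + stats::rnorm(length(v), 0, sigma_px * pixel_scale)
  out <- displacement_trace(trace$times, v, pixel_scale = pixel_scale)
  attr(out, "noise") <- list(pixel_scale = pixel_scale, sigma_px = sigma_px,
                             seed = seed)
  out
}
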