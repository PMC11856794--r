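# Bioreactor stimulus timelines: cyclic mechanical stretch (half-sine
# pulses from the cam mechanism) coordinated with rectangular electrical
# pulses, one pulse pair per motor rotation.

#' Bioreactor stimulus schedule
#'
#' Encodes the coordinated mechanical/electrical stimulation parameters.
#' The motor rate gamma fixes the stretch frequency (f_m = gamma), the
#' stimulus period (P_s = 1/gamma) and the electrical period
#' (P_e = P_s; each motor rotation triggers one electrical pulse).
#' Operating defaults: 1 rotation/s, stretch width 0.5 s, maximum strain
#' 0.05, pulse amplitude 100 mV, pulse width 1 ms, zero phase.
#'
#' @param gamma Motor rotation rate in rotations/s.
#' @param tau Stretch pulse width in seconds (about half the period).
#' @param eps_m Maximum stretch strain (dimensionless).
#' @param E_m Electrical pulse amplitude in mV.
#' @param upsilon Electrical pulse width in ms.
#' @param delta Phase of the electrical pulse after each stretch onset,
#'   in ms (0 <= delta < 1000 P_s).
#' @return A list of class \code{"stimulus_schedule"} with the derived
#'   identities \code{f_m = gamma}, \code{P_s = 1/gamma}, \code{P_e = P_s},
#'   \code{f_e = f_m}.
#' @export
stimulus_schedule <- function(gamma = 1.0, tau = NULL, eps_m = 0.05,
                              E_m = 100, upsilon = 1.0, delta = 0) {
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  P_s <- 1 / gamma
  if (is.null(tau)) tau <- 0.5 * P_s
  if (tau <= 0 || tau > P_s)
    stop("'tau' must lie in (0, P_s]", call. = FALSE)
  if (delta < 0 || delta >= P_s * 1000)
    stop("'delta' must satisfy 0 <= delta < 1000 P_s (ms)", call. = FALSE)
  if (upsilon < 0 || upsilon > P_s * 1000)
    stop("'upsilon' must satisfy 0 <= upsilon <= 1000 P_e (ms)",
         call. = FALSE)
  structure(list(gamma = gamma, f_m = gamma, P_s = P_s, tau = tau,
                 eps_m = eps_m, E_m = E_m, P_e = P_s, f_e = gamma,
                 upsilon = upsilon, delta = delta),
            class = "stimulus_schedule")
}

#' Sampled stretch and pulse waveforms for a schedule
#'
#' The mechanical strain is a half-sine pulse of width \code{tau} and peak
#' \code{eps_m} at the start of each period; the electrical stimulus is a
#' rectangular pulse of amplitude \code{E_m} and width \code{upsilon},
#' offset by \code{delta} from each stretch onset.
#'
#' @param sched A \code{\link{stimulus_schedule}}.
#' @param duration Timeline length in seconds.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @return A data frame with columns \code{time_s}, \code{strain},
#'   \code{pulse_mV}.
#' @export
stimulus_timeline <- function(sched, duration, sample_rate = 1000) {
  stopifnot(inherits(sched, "stimulus_schedule"))
  # half-open [0, duration): exactly duration * sample_rate samples, so a
  # whole number of periods holds a whole number of pulses
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  u <- t %% sched$P_s
  strain <- ifelse(u < sched$tau,
                   sched$eps_m * sin(pi * u / sched$tau), 0)
  ue <- (t - sched$delta / 1000) %% sched$P_e
  pulse <- ifelse(ue >= 0 & ue < sched$upsilon / 1000, sched$E_m, 0)
  data.frame(time_s = t, strain = strain, pulse_mV = pulse)
}

#' Inspect a stimulus timeline
#'
#' Counts stretch and electrical pulses and reports peak values and
#' measured widths, for verifying that a schedule produces exactly one
#' coordinated stretch/pulse pair per period.
#'
#' @param timeline A \code{\link{stimulus_timeline}} data frame.
#' @return A list with \code{n_stretch}, \code{n_pulse} (pulse counts),
#'   \code{strain_peak}, \code{pulse_peak_mV}, \code{stretch_width_s} and
#'   \code{pulse_width_s} (mean widths at half onset).
#' @export
stimulus_summary <- function(timeline) {
  stopifnot(all(c("time_s", "strain", "pulse_mV") %in% names(timeline)))
  dt <- mean(diff(timeline$time_s))
  count_runs <- function(on) {
    r <- rle(on)
    sum(r$values)
  }
  on_s <- timeline$strain > 0
  on_e <- timeline$pulse_mV > 0
  width <- function(on) {
    r <- rle(on)
    w <- r$lengths[r$values]
    if (length(w)) mean(w) * dt else 0
  }
  list(n_stretch = count_runs(on_s), n_pulse = count_runs(on_e),
       strain_peak = max(timeline$strain),
       pulse_peak_mV = max(timeline$pulse_mV),
       stretch_width_s = width(on_s), pulse_width_s = width(on_e))
}
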