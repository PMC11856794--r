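# Displacement -> force reconstruction: the inverse problem.  Each retained
# displacement harmonic is mapped through the analytic beam mode to the tip
# shear-force amplitude; the DC term maps through the static stiffness.
#   B(t) = 3 S0 EI / (2 L^3) + sum_j A_j cos(omega_j t + phi_j),
# where A_j is the tip shear amplitude of harmonic j.  The third spatial
# derivative is evaluated analytically from the modal solution, never by
# finite-differencing the (pixel-quantized) displacement record.

#' Reconstructed beating-force trace
#'
#' Container for a force time series on the same uniform grid contract as
#' \code{\link{displacement_trace}}.
#'
#' @param times Times in seconds (uniform grid).
#' @param values Force in newtons.
#' @param provenance Named list describing how the trace was produced.
#' @return An object of class \code{"force_trace"}.
#' @export
force_trace <- function(times, values, provenance = list(source = "unknown")) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("force values must be finite", call. = FALSE)
  if (length(provenance) == 0)
    stop("'provenance' must be non-empty", call. = FALSE)
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)))
    stop("'times' must be a strictly increasing uniform grid", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 fs = if (length(dt)) 1 / mean(dt) else NA_real_,
                 provenance = provenance),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "Force trace: %d samples at %.6g Hz, range [%.4g, %.4g] uN\n",
    length(x$values), x$fs, min(x$values) * 1e6, max(x$values) * 1e6))
  invisible(x)
}

#' Read / write force traces as CSV (columns time_s, force_N)
#' @param path File path.
#' @return \code{read_force} returns a \code{\link{force_trace}}.
#' @export
read_force <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(d)))
    stop("force CSV must have columns time_s, force_N", call. = FALSE)
  force_trace(d$time_s, d$force_N, provenance = list(source = path))
}

#' @rdname read_force
#' @param force A \code{\link{force_trace}}.
#' @export
write_force <- function(force, path) {
  stopifnot(inherits(force, "force_trace"))
  utils::write.csv(data.frame(time_s = force$times, force_N = force$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Static tip force for a held deflection
#'
#' The calibration closed form: a transverse point load P at the free end
#' deflects the tip by delta = P L^3 / (3 EI), so \code{static_force}
#' returns 3 EI delta / L^3.
#'
#' @param delta Tip deflection in metres (vectorised).
#' @param spec A \code{\link{cantilever}} object.
#' @return Force in newtons.
#' @export
static_force <- function(delta, spec) {
  stopifnot(inherits(spec, "cantilever"))
  3 * spec$EI * delta / spec$length^3
}

#' Quasi-static force baseline
#'
#' Maps the displacement trace pointwise through the static stiffness
#' 3EI/L^3. Used as a diagnostic baseline: the relative departure of the
#' dynamic reconstruction from this curve measures how much the inertial
#' terms matter for the given probe and beating rate.
#'
#' @param trace A \code{\link{displacement_trace}}.
#' @param spec A \code{\link{cantilever}}.
#' @return A \code{\link{force_trace}}.
#' @export
quasistatic_force <- function(trace, spec) {
  stopifnot(inherits(trace, "displacement_trace"))
  force_trace(trace$times, static_force(trace$values, spec),
              provenance = list(source = "quasistatic_force"))
}

#' Reconstruct the beating force from a tip-displacement trace
#'
#' The central estimator of the package. The displacement record is
#' Fourier-decomposed; each retained harmonic is propagated through the
#' analytic clamped/prescribed-tip beam mode to the shear force at the
#' hook end; the harmonic force amplitudes are superposed with the static
#' calibration term to give the beating-force waveform
#' \code{B(t) = 3 S0 EI / (2 L^3) + sum_j A_j cos(omega_j t + phi_j)}.
#'
#' Harmonics at or above \code{guard} times the first clamped-pinned
#' resonance of the probe are dropped (the inversion is singular at the
#' resonance); if a retained harmonic still lands inside the singularity
#' band an error identifies the offending frequency.
#'
#' @param trace A \code{\link{displacement_trace}}, or a data frame with
#'   columns \code{time_s} and \code{displacement_m} (or
#'   \code{displacement_px} together with \code{pixel_scale}).
#' @param spec A \code{\link{cantilever}} describing the probe.
#' @param max_harmonics,amp_floor,integer_periods Passed to
#'   \code{\link{spectral_decompose}}.
#' @param guard Resonance guard as a fraction of the first clamped-pinned
#'   resonance frequency (default 0.8).
#' @param pixel_scale Metres per pixel, required when \code{trace} is a
#'   data frame in pixels.
#' @return An object of class \code{"beat_force"}: a list with the input
#'   \code{trace}, the \code{spec}, the \code{decomposition}, the
#'   harmonic force amplitudes \code{force_harmonics}, the reconstructed
#'   \code{force} (\code{\link{force_trace}} on the analysis window), the
#'   static term \code{static_term} (N), the quasi-static baseline and the
#'   \code{dynamic_correction} (relative RMS departure from it), and the
#'   \code{call}. Methods: \code{print}, \code{summary} (beat kinetics),
#'   \code{coef}, \code{plot}, \code{fitted}, \code{residuals},
#'   \code{predict}.
#' @examples
#' cl <- compliant_cantilever()
#' tw <- twitch_force(twitch_params("ventricular"), seq(0, 10, by = 1/60))
#' tr <- displacement_trace(tw$times, tw$values / (3 * cl$EI / cl$length^3))
#' fit <- beat_force(tr, cl)
#' summary(fit)
#' @export
beat_force <- function(trace, spec, max_harmonics = 25L, amp_floor = 1e-3,
                       integer_periods = TRUE, guard = 0.8,
                       pixel_scale = NULL) {
  cl <- match.call()
  stopifnot(inherits(spec, "cantilever"))
  if (is.data.frame(trace)) {
    if ("displacement_m" %in% names(trace)) {
      trace <- displacement_trace(trace$time_s, trace$displacement_m,
                                  pixel_scale = pixel_scale)
    } else if ("displacement_px" %in% names(trace)) {
      if (is.null(pixel_scale))
        stop("displacement is in pixels: 'pixel_scale' (m/px) is required",
             call. = FALSE)
      trace <- displacement_trace(trace$time_s,
                                  trace$displacement_px * pixel_scale,
                                  pixel_scale = pixel_scale)
    } else {
      stop("data-frame input needs 'time_s' and 'displacement_m' (or '_px')",
           call. = FALSE)
    }
  }
  stopifnot(inherits(trace, "displacement_trace"))

  omega_res <- 2 * pi * clamped_pinned_frequency(spec)
  dec <- spectral_decompose(trace, max_harmonics = max_harmonics,
                            amp_floor = amp_floor,
                            omega_max = guard * omega_res,
                            integer_periods = integer_periods)

  h <- dec$harmonics
  amps <- numeric(nrow(h))
  for (i in seq_len(nrow(h))) {
    mc <- modal_coefficients(h$S[i], h$omega[i], h$phi[i], spec)
    if (mc$singular)
      stop(sprintf(
        "retained harmonic at %.4g Hz lies in the resonance singularity band",
        h$omega[i] / (2 * pi)), call. = FALSE)
    amps[i] <- tip_shear_amplitude(mc, spec)
  }

  static_term <- 3 * dec$S0 * spec$EI / (2 * spec$length^3)
  times <- trace$times[seq_len(dec$n_used)]
  tt <- times - dec$t0
  B <- rep(static_term, length(times))
  for (i in seq_len(nrow(h)))
    B <- B + amps[i] * cos(h$omega[i] * tt + h$phi[i])

  prov <- list(source = "beat_force",
               spec = unclass(spec)[c("length", "diameter", "density",
                                      "modulus")],
               max_harmonics = max_harmonics, amp_floor = amp_floor,
               guard = guard, dropped_energy = dec$dropped_energy)
  force <- force_trace(times, B, provenance = prov)

  qs <- static_force(trace$values[seq_len(dec$n_used)], spec)
  denom <- max(abs(B))
  dyn <- if (denom > 0) sqrt(mean((B - qs)^2)) / denom else 0

  structure(list(trace = trace, spec = spec, decomposition = dec,
                 force_harmonics = data.frame(
                   j = h$j, omega = h$omega, S = h$S, phi = h$phi,
                   amplitude_N = amps),
                 force = force, static_term = static_term,
                 quasistatic = qs, dynamic_correction = dyn,
                 call = cl),
            class = "beat_force")
}
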