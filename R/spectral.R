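# Conversion between a uniformly sampled tip-displacement record and its
# truncated real Fourier series  s(t) = S0/2 + sum_j S_j cos(omega_j t + phi_j),
# the form in which the beam inversion consumes the measurement.

#' Uniformly sampled tip-displacement trace
#'
#' @param times Sample times in seconds, strictly increasing on a uniform
#'   grid (relative spacing jitter below 1e-9 is tolerated).
#' @param values Tip displacement in metres, relative to the unloaded
#'   cantilever position (the DC offset carries the static pre-stretch and
#'   is used by the calibration term of the reconstruction).
#' @param pixel_scale Optional provenance: metres per pixel if the values
#'   were converted from pixels.
#' @return An object of class \code{"displacement_trace"}: a list with
#'   \code{times}, \code{values}, sample rate \code{fs} (Hz) and
#'   \code{pixel_scale}.
#' @export
displacement_trace <- function(times, values, pixel_scale = NULL) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-9 * mean(dt) * max(1, abs(mean(times))))
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("'times' must be a uniform grid", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 fs = 1 / mean(dt), pixel_scale = pixel_scale),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(
    "Displacement trace: %d samples at %.6g Hz (%.4g s), range [%.4g, %.4g] um\n",
    length(x$values), x$fs, diff(range(x$times)),
    min(x$values) * 1e6, max(x$values) * 1e6))
  invisible(x)
}

#' Read / write displacement traces as CSV
#'
#' The interchange format is a headed CSV with columns \code{time_s} and
#' \code{displacement_m}, or \code{time_s} and \code{displacement_px} with
#' a pixel scale supplied at read time.
#'
#' @param path File path.
#' @param pixel_scale Metres per pixel; required if the file stores
#'   \code{displacement_px}.
#' @return \code{read_trace} returns a \code{\link{displacement_trace}};
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
read_trace <- function(path, pixel_scale = NULL) {
  d <- utils::read.csv(path)
  if (!"time_s" %in% names(d))
    stop("trace CSV must have a 'time_s' column", call. = FALSE)
  if ("displacement_m" %in% names(d)) {
    displacement_trace(d$time_s, d$displacement_m, pixel_scale = pixel_scale)
  } else if ("displacement_px" %in% names(d)) {
    if (is.null(pixel_scale))
      stop("trace is in pixels: a 'pixel_scale' (m/px) is required",
           call. = FALSE)
    displacement_trace(d$time_s, d$displacement_px * pixel_scale,
                       pixel_scale = pixel_scale)
  } else {
    stop("trace CSV must have 'displacement_m' or 'displacement_px'",
         call. = FALSE)
  }
}

#' @rdname read_trace
#' @param trace A \code{\link{displacement_trace}}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "displacement_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, displacement_m = trace$values),
    path, row.names = FALSE)
  invisible(path)
}

#' Fourier decomposition of a displacement record
#'
#' Computes the truncated real Fourier series of the record:
#' \code{S0/2 + sum_j S_j cos(omega_j t + phi_j)} with
#' \code{omega_j = 2 pi j / T_rec}. The record is first truncated to an
#' integer number of beat periods (period estimated from the dominant
#' non-DC harmonic) to suppress spectral leakage, unless
#' \code{integer_periods = FALSE}. Harmonics weaker than
#' \code{amp_floor} times the strongest harmonic are dropped; if
#' \code{omega_max} is given (the reconstruction's resonance guard),
#' harmonics at or above it are always dropped with a warning.
#'
#' @param trace A \code{\link{displacement_trace}} (>= 4 samples).
#' @param max_harmonics Maximum number of harmonics retained, counted in
#'   multiples of the dominant (beat) frequency (default 25): a record
#'   holding m beat cycles keeps DFT bins up to \code{25 m}, i.e. content
#'   up to 25 times the beat rate regardless of record length.
#' @param amp_floor Relative amplitude floor (default 1e-3).
#' @param omega_max Optional angular-frequency cut (rad/s); harmonics with
#'   \code{omega_j >= omega_max} are dropped with a warning.
#' @param integer_periods Truncate to an integer number of estimated beat
#'   periods before the DFT (default TRUE).
#' @return An object of class \code{"spectral_decomposition"}: list with
#'   \code{S0} (m; the constant offset of the series is S0/2), data frame
#'   \code{harmonics} (\code{j, S, omega, phi}), \code{T_rec} (s),
#'   \code{t0} (time origin of the analysis window), \code{n_used}
#'   (samples analysed), \code{dropped_energy} (fraction of record
#'   variance not carried by the retained harmonics).
#' @export
spectral_decompose <- function(trace, max_harmonics = 25L, amp_floor = 1e-3,
                               omega_max = NULL, integer_periods = TRUE) {
  stopifnot(inherits(trace, "displacement_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 4L) stop("trace must have at least 4 samples", call. = FALSE)
  dt <- 1 / trace$fs

  cycles <- 1L                                # beat cycles in the window
  z0 <- stats::fft(x - mean(x))
  mag <- Mod(z0[2:(n %/% 2)])
  if (length(mag) && max(mag) > 0) {
    jdom <- which.max(mag)                    # cycles over the full record
    per <- round(n / jdom)                    # samples per dominant period
    if (per >= 2 && per <= n) {
      if (integer_periods) {
        n_use <- (n %/% per) * per
        x <- x[seq_len(n_use)]
        n <- n_use
      }
      cycles <- max(1L, n %/% per)
    }
  }

  z <- stats::fft(x) / n
  nyq <- n %/% 2
  jmax <- min(max_harmonics * cycles, nyq - 1L)
  if (jmax < 0L) jmax <- 0L
  S0 <- 2 * Re(z[1L])
  j <- seq_len(jmax)
  S <- 2 * Mod(z[j + 1L])
  phi <- Arg(z[j + 1L])
  T_rec <- n * dt
  omega <- 2 * pi * j / T_rec

  var_tot <- mean((x - mean(x))^2)            # total AC power
  keep <- rep(TRUE, length(j))
  scale_x <- max(abs(x), .Machine$double.xmin)
  if (length(S)) {
    if (max(S) <= 1e-13 * scale_x) {
      keep <- rep(FALSE, length(j))   # numerically constant record
    } else {
      keep <- S >= amp_floor * max(S)
    }
  }
  if (!is.null(omega_max)) {
    hot <- omega >= omega_max
    if (any(hot & keep))
      warning(sprintf(
        "%d harmonic(s) at/above the resonance guard (%.4g Hz) dropped",
        sum(hot & keep), omega_max / (2 * pi)), call. = FALSE)
    keep <- keep & !hot
  }
  kept_power <- sum(S[keep]^2) / 2
  dropped <- if (var_tot > 0) max(0, 1 - kept_power / var_tot) else 0

  structure(list(
    S0 = S0,
    harmonics = data.frame(j = j[keep], S = S[keep],
                           omega = omega[keep], phi = phi[keep]),
    T_rec = T_rec, t0 = trace$times[1L], n_used = n,
    dropped_energy = dropped),
    class = "spectral_decomposition")
}

#' Evaluate a Fourier decomposition on a time grid
#'
#' @param decomp A \code{\link{spectral_decompose}} result.
#' @param times Times in seconds (absolute; the decomposition's own time
#'   origin is honoured).
#' @return Displacement values in metres,
#'   \code{S0/2 + sum_j S_j cos(omega_j (t - t0) + phi_j)}.
#' @export
spectral_reconstruct <- function(decomp, times) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  out <- rep(decomp$S0 / 2, length(times))
  h <- decomp$harmonics
  tt <- times - decomp$t0
  for (i in seq_len(nrow(h)))
    out <- out + h$S[i] * cos(h$omega[i] * tt + h$phi[i])
  out
}
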