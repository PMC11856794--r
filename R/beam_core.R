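# Analytic machinery for the forced transverse vibration of a clamped
# cantilever whose tip displacement is prescribed harmonically.
#
# For each harmonic S cos(omega t + phi) of the tip displacement, separation
# of variables gives the spatial mode
#   y(x) = C1 (cosh kx - cos kx) + C2 (sinh kx - sin kx)
# satisfying y(0) = y'(0) = 0 by construction; the remaining conditions
# y(L) = S and y''(L) = 0 fix C1, C2 through the determinant
#   D(kappa) = (cosh kappa - cos kappa)(sinh kappa + sin kappa)
#            - (cosh kappa + cos kappa)(sinh kappa - sin kappa)
#            = 2 (cosh kappa sin kappa - cos kappa sinh kappa),
# kappa = kL. D vanishes at the clamped-pinned eigenvalues (tan k = tanh k),
# where the inversion is ill-posed.

# determinant of the modal boundary system, kappa = k L
mode_determinant <- function(kappa) {
  2 * (cosh(kappa) * sin(kappa) - cos(kappa) * sinh(kappa))
}

# scale-aware singularity threshold: away from roots |D| ~ cosh(kappa) for
# large kappa and ~ 4 kappa^3 / 3 as kappa -> 0 (where small |D| is the
# regular quasi-static limit, not a resonance)
default_singular_tol <- function(kappa) {
  1e-6 * cosh(kappa) * kappa^3 / (1 + kappa^3)
}

#' Modal coefficients for a prescribed-tip-displacement harmonic
#'
#' Computes the spatial-mode coefficients C1, C2 for one harmonic of the
#' measured tip displacement, S cos(omega t + phi), on the given cantilever.
#' The mode satisfies the clamped-end conditions y(0) = y'(0) = 0 and the
#' tip conditions y(L) = S (prescribed displacement) and y''(L) = 0 (the
#' gel hook transmits no moment).
#'
#' @param S Harmonic displacement amplitude in metres.
#' @param omega Angular frequency in rad/s (>= 0).
#' @param phi Phase in radians.
#' @param spec A \code{\link{cantilever}} object.
#' @param tol Singularity tolerance for the boundary determinant; default is
#'   scale-aware, \code{1e-6 * cosh(kappa)}.
#' @return A list of class \code{"modal_coefficients"} with fields \code{k}
#'   (wavenumber, 1/m), \code{kappa} (= kL), \code{S}, \code{omega},
#'   \code{phi}, \code{C1}, \code{C2} (m), \code{D} (determinant) and
#'   \code{singular} (logical).
#' @export
modal_coefficients <- function(S, omega, phi = 0, spec, tol = NULL) {
  stopifnot(inherits(spec, "cantilever"))
  if (!is.finite(S)) stop("'S' must be finite", call. = FALSE)
  k <- wavenumber(omega, spec)
  kappa <- k * spec$length
  D <- mode_determinant(kappa)
  if (is.null(tol)) tol <- default_singular_tol(kappa)
  singular <- abs(D) < tol
  if (singular && S != 0)
    warning(sprintf(
      "harmonic at %.4g Hz is within the resonance singularity band (|D| = %.3g); reconstruction is ill-posed there",
      omega / (2 * pi), abs(D)), call. = FALSE)
  if (S == 0 || kappa == 0) {
    C1 <- C2 <- 0
  } else if (singular) {
    C1 <- C2 <- NA_real_
  } else {
    C1 <- S * (sinh(kappa) + sin(kappa)) / D
    C2 <- -S * (cosh(kappa) + cos(kappa)) / D
  }
  structure(list(k = k, kappa = kappa, S = S, omega = omega, phi = phi,
                 C1 = C1, C2 = C2, D = D, singular = singular),
            class = "modal_coefficients")
}

#' Evaluate a spatial mode and its derivatives
#'
#' @param mc A \code{\link{modal_coefficients}} object.
#' @param x Positions along the beam in metres.
#' @param deriv Derivative order 0..3.
#' @return Mode value (or spatial derivative) at \code{x}.
#' @export
mode_shape <- function(mc, x, deriv = 0L) {
  stopifnot(inherits(mc, "modal_coefficients"), deriv %in% 0:3)
  if (mc$singular && !is.finite(mc$C1))
    stop("mode is singular (resonant harmonic); coefficients undefined",
         call. = FALSE)
  k <- mc$k
  if (k == 0) {                        # static/DC harmonic: flat mode
    return(if (deriv == 0L) rep(mc$S, length(x)) else rep(0, length(x)))
  }
  kx <- k * x
  f <- switch(deriv + 1L,
    mc$C1 * (cosh(kx) - cos(kx)) + mc$C2 * (sinh(kx) - sin(kx)),
    k   * (mc$C1 * (sinh(kx) + sin(kx)) + mc$C2 * (cosh(kx) - cos(kx))),
    k^2 * (mc$C1 * (cosh(kx) + cos(kx)) + mc$C2 * (sinh(kx) + sin(kx))),
    k^3 * (mc$C1 * (sinh(kx) - sin(kx)) + mc$C2 * (cosh(kx) + cos(kx))))
  f
}

#' Tip shear-force amplitude for one harmonic
#'
#' The internal shear force at the hook end is the force the gel exerts on
#' the probe. For the harmonic with modal coefficients \code{mc} the
#' amplitude is \code{-EI * y'''(L)}; the sign convention makes the
#' quasi-static limit equal +3 EI S / L^3 (a positive displacement toward
#' the gel reports a positive pulling force).
#'
#' @param mc A \code{\link{modal_coefficients}} object (non-singular).
#' @param spec The \code{\link{cantilever}} used to build \code{mc}.
#' @return Force amplitude in newtons.
#' @export
tip_shear_amplitude <- function(mc, spec) {
  stopifnot(inherits(mc, "modal_coefficients"), inherits(spec, "cantilever"))
  if (mc$S == 0) return(0)
  if (mc$singular)
    stop(sprintf(
      "harmonic at %.4g Hz is resonant (|D| = %.3g); tip shear undefined",
      mc$omega / (2 * pi), abs(mc$D)), call. = FALSE)
  if (mc$kappa == 0) return(3 * spec$EI * mc$S / spec$length^3)
  -spec$EI * mode_shape(mc, spec$length, deriv = 3L)
}

# closed-form displacement->force transfer H(omega) = amplitude / S, in N/m.
# Algebraic reduction of tip_shear_amplitude:
#   H = EI k^3 (1 + cosh kappa cos kappa) / (cosh kappa sin kappa
#                                            - cos kappa sinh kappa)
# Quasi-static limit 3EI/L^3; zero at the clamped-free eigenvalue
# (kappa = 1.8751); pole at the clamped-pinned eigenvalue (kappa = 3.9266).
# Exponential rescaling by cosh(kappa) avoids overflow for large kappa.
tip_transfer <- function(omega, spec) {
  k <- wavenumber(omega, spec)
  kappa <- k * spec$length
  H <- numeric(length(kappa))
  small <- kappa < 1e-4
  H[small] <- 3 * spec$EI / spec$length^3
  kb <- kappa[!small]
  num <- ifelse(kb > 20, 1 / cosh(kb) + cos(kb), 1 + cosh(kb) * cos(kb))
  den <- ifelse(kb > 20, sin(kb) - cos(kb) * tanh(kb),
                cosh(kb) * sin(kb) - cos(kb) * sinh(kb))
  H[!small] <- spec$EI * k[!small]^3 * num / den
  H
}

#' Resonance roots of the modal determinant
#'
#' Returns the first \code{n} positive roots (in kappa = kL) of
#' cosh(k) sin(k) - cos(k) sinh(k) = 0, equivalently tan(k) = tanh(k):
#' the clamped-pinned beam eigenvalues at which the prescribed-tip
#' inversion is singular. The first two roots are approximately 3.9266
#' and 7.0686.
#'
#' @param spec A \code{\link{cantilever}} object (unused by the
#'   dimensionless root search; accepted so callers can pass their probe).
#' @param n Number of roots (>= 1).
#' @return Ascending numeric vector of kappa roots.
#' @export
resonance_wavenumbers <- function(spec = NULL, n = 2L) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  # rescaled determinant tan(k) - tanh(k) shares the roots and is well
  # behaved between poles of tan; root i lies in (i pi, i pi + pi/2)
  f <- function(k) sin(k) - cos(k) * tanh(k)
  vapply(seq_len(n), function(i) {
    stats::uniroot(f, c(i * pi + 1e-9, i * pi + pi / 2 - 1e-9),
                   tol = 1e-13)$root
  }, numeric(1))
}
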