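#' Cantilever probe specification
#'
#' Describes the geometry and material of the thin circular wire used as a
#' force probe: one end is clamped, the free end is hooked to the tissue gel.
#' Derived section properties (cross-sectional area, second moment of area,
#' flexural rigidity) are computed on construction.
#'
#' Defaults correspond to a 0.2 mm diameter silver wire (density
#' 10.5 g/cm^3, elastic modulus 83 GPa). The free length \code{length} is
#' instrument-specific and must be supplied for real measurements; the
#' default of 10 mm is a synthetic working value.
#'
#' @param length Free length L of the cantilever in metres.
#' @param diameter Wire diameter d in metres.
#' @param density Material density in kg/m^3.
#' @param modulus Elastic (Young's) modulus in Pa.
#' @return An object of class \code{"cantilever"}: a list with fields
#'   \code{length}, \code{diameter}, \code{density}, \code{modulus} and the
#'   derived \code{area} (pi d^2/4), \code{second_moment} (pi d^4/64) and
#'   \code{EI} (flexural rigidity, N m^2).
#' @examples
#' cl <- cantilever()
#' cl$EI                      # ~6.52e-6 N m^2 for the silver wire
#' static_force(1e-6, cl)     # ~19.6 uN for a 1 um held deflection
#' @export
cantilever <- function(length = 0.01, diameter = 2e-4,
                       density = 10500, modulus = 8.3e10) {
  for (nm in c("length", "diameter", "density", "modulus")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  sp <- section_properties(diameter)
  structure(list(length = length, diameter = diameter,
                 density = density, modulus = modulus,
                 area = sp[["area"]], second_moment = sp[["second_moment"]],
                 EI = modulus * sp[["second_moment"]]),
            class = "cantilever")
}

#' Section properties of a circular wire
#'
#' @param diameter Wire diameter in metres (positive).
#' @return Named numeric vector with \code{area} = pi d^2/4 (m^2) and
#'   \code{second_moment} = pi d^4/64 (m^4).
#' @export
section_properties <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be a single positive finite number", call. = FALSE)
  c(area = pi * diameter^2 / 4, second_moment = pi * diameter^4 / 64)
}

#' Flexural wavenumber of a vibrating beam
#'
#' For transverse vibration at angular frequency omega, the spatial
#' wavenumber is k = (rho A omega^2 / (E I))^(1/4).
#'
#' @param omega Angular frequency in rad/s (vectorised, each >= 0).
#' @param spec A \code{\link{cantilever}} object.
#' @return Wavenumber(s) in 1/m; \code{wavenumber(0, spec) == 0}.
#' @export
wavenumber <- function(omega, spec) {
  stopifnot(inherits(spec, "cantilever"))
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0))
    stop("'omega' must be finite and non-negative", call. = FALSE)
  (spec$density * spec$area * omega^2 / spec$EI)^0.25
}

#' First clamped-free natural frequency (Hz)
#'
#' f1 = (1.8751^2 / (2 pi)) sqrt(EI / (rho A)) / L^2. This is the frequency
#' at which the beam vibrates with no tip force; the displacement-to-force
#' transfer function has a zero here.
#'
#' @param spec A \code{\link{cantilever}} object.
#' @param n Number of frequencies to return (default 1).
#' @return Natural frequencies in Hz (ascending).
#' @export
clamped_free_frequency <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "cantilever"))
  kappa <- free_vibration_roots(n)
  kappa^2 / (2 * pi) * sqrt(spec$EI / (spec$density * spec$area)) /
    spec$length^2
}

#' Clamped-pinned resonance frequencies (Hz)
#'
#' Frequencies where the determinant of the prescribed-tip-displacement
#' modal system vanishes (roots of tan k = tanh k); the inverse force
#' reconstruction is singular there.
#'
#' @inheritParams clamped_free_frequency
#' @return Resonance frequencies in Hz (ascending).
#' @export
clamped_pinned_frequency <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "cantilever"))
  kappa <- resonance_wavenumbers(spec, n)
  kappa^2 / (2 * pi) * sqrt(spec$EI / (spec$density * spec$area)) /
    spec$length^2
}

# roots of cosh(k) cos(k) + 1 = 0 (clamped-free eigenvalues), ascending
free_vibration_roots <- function(n) {
  f <- function(k) 1 + cosh(k) * cos(k)
  roots <- numeric(n)
  # asymptotically near (2i-1) pi/2; first root ~1.8751
  for (i in seq_len(n)) {
    lo <- max(1e-3, (2 * i - 1) * pi / 2 - 1)
    hi <- (2 * i - 1) * pi / 2 + 1
    roots[i] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  roots
}

#' @export
print.cantilever <- function(x, ...) {
  cat("Cantilever probe\n")
  cat(sprintf("  length      : %.4g mm\n", x$length * 1e3))
  cat(sprintf("  diameter    : %.4g mm\n", x$diameter * 1e3))
  cat(sprintf("  density     : %.4g kg/m^3\n", x$density))
  cat(sprintf("  modulus     : %.4g GPa\n", x$modulus / 1e9))
  cat(sprintf("  EI          : %.4g N m^2\n", x$EI))
  cat(sprintf("  stiffness   : %.4g N/m (3EI/L^3)\n", 3 * x$EI / x$length^3))
  cat(sprintf("  f1 (free)   : %.4g Hz\n", clamped_free_frequency(x)))
  cat(sprintf("  f1 (pinned) : %.4g Hz (inversion resonance)\n",
              clamped_pinned_frequency(x)))
  invisible(x)
}

#' Read / write a cantilever specification as JSON
#'
#' The JSON schema uses explicit SI-unit field names:
#' \code{{"length_m", "diameter_m", "density_kg_m3", "modulus_pa"}}.
#'
#' @param path File path.
#' @return \code{read_cantilever} returns a \code{\link{cantilever}};
#'   \code{write_cantilever} returns \code{path} invisibly.
#' @export
read_cantilever <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("length_m", "diameter_m", "density_kg_m3", "modulus_pa")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("cantilever JSON missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cantilever(length = j$length_m, diameter = j$diameter_m,
             density = j$density_kg_m3, modulus = j$modulus_pa)
}

#' @rdname read_cantilever
#' @param spec A \code{\link{cantilever}} object.
#' @export
write_cantilever <- function(spec, path) {
  stopifnot(inherits(spec, "cantilever"))
  jsonlite::write_json(
    list(length_m = spec$length, diameter_m = spec$diameter,
         density_kg_m3 = spec$density, modulus_pa = spec$modulus),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compliant demonstration probe
#'
#' Same silver wire as the default but with a 0.1 m free length, bringing the
#' first clamped-free natural frequency down to about 7.9 Hz so that beating
#' at physiological rates excites genuinely dynamic (non-quasi-static)
#' behaviour. Used for exercising the dynamic terms of the reconstruction.
#'
#' @return A \code{\link{cantilever}} object.
#' @export
compliant_cantilever <- function() cantilever(length = 0.1)
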