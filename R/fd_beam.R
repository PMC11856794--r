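# Independent forward simulator of the beam equation
#   rho A y_tt = -EI y_xxxx + tip force,
# used as the verification oracle for the analytic inversion.  Spatial
# discretization: second-order central differences with ghost nodes
# enforcing y = y' = 0 at the clamp and y'' = 0, EI y''' = -F(t) at the
# free end.  Time integration: Newmark average-acceleration (implicit,
# unconditionally stable, no numerical damping), so the step size is
# chosen to resolve the forcing content rather than the stiff upper beam
# modes.  The simulator shares no modal code with the analytic machinery.

#' Forward beam-simulation configuration
#'
#' @param n_x Number of spatial intervals (default 50).
#' @param dt Time step in seconds (default 2e-4, resolving forcing content
#'   up to several hundred Hz; reduce to resolve free vibration of stiff
#'   probes).
#' @param duration Simulated time in seconds (default: span of the applied
#'   force trace).
#' @param damping_mass Mass-proportional damping coefficient (1/s,
#'   default 0).
#' @param damping_stiff Stiffness-proportional damping coefficient (s,
#'   default 0). Used only to test inversion robustness against
#'   unmodelled dissipation.
#' @param seed RNG seed recorded in outputs (the simulator itself is
#'   deterministic).
#' @param output_fs Output sampling rate for the tip trace in Hz
#'   (default 60, the camera frame rate).
#' @return A list of class \code{"beam_sim_config"}.
#' @export
beam_sim_config <- function(n_x = 50L, dt = 2e-4, duration = NULL,
                            damping_mass = 0, damping_stiff = 0,
                            seed = 1L, output_fs = 60) {
  if (n_x < 10L) stop("'n_x' must be at least 10", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (output_fs <= 0) stop("'output_fs' must be positive", call. = FALSE)
  structure(list(n_x = as.integer(n_x), dt = dt, duration = duration,
                 damping_mass = damping_mass, damping_stiff = damping_stiff,
                 seed = as.integer(seed), output_fs = output_fs),
            class = "beam_sim_config")
}

# stiffness matrix (EI/dx^4 scaled) and tip-force load vector for the
# ghost-node discretization; unknowns are nodes 1..N (clamp node 0
# eliminated).  Returns list(K, b) with M = rhoA * I implied.
.beam_matrices <- function(spec, n_x) {
  N <- n_x
  dx <- spec$length / N
  c4 <- spec$EI / dx^4
  K <- matrix(0, N, N)
  add <- function(i, j, v) if (j >= 1L && j <= N) K[i, j] <<- K[i, j] + v
  for (i in 1:N) {
    # base stencil y[i-2] - 4 y[i-1] + 6 y[i] - 4 y[i+1] + y[i+2]
    st <- c(1, -4, 6, -4, 1)
    idx <- (i - 2L):(i + 2L)
    if (i == 1L) {          # ghost y[-1] = y[1] (clamp slope), y[0] = 0
      add(1L, 1L, st[1])    # y[-1] -> y[1]
      for (m in 3:5) add(1L, idx[m], st[m])
    } else if (i == N - 1L) {  # ghost y[N+1] = 2 y[N] - y[N-1]
      for (m in 1:4) add(i, idx[m], st[m])
      add(i, N, 2); add(i, N - 1L, -1)
    } else if (i == N) {
      # ghosts: y[N+1] = 2 y[N] - y[N-1]
      #         y[N+2] = 2 y[N+1] - 2 y[N-1] + y[N-2] - 2 dx^3 F / EI
      for (m in 1:3) add(i, idx[m], st[m])
      add(i, N, -4 * 2); add(i, N - 1L, -4 * -1)         # -4 y[N+1]
      add(i, N, 2 * 2); add(i, N - 1L, 2 * -1 - 2)       # y[N+2] parts
      add(i, N - 2L, 1)
      # the -2 dx^3 F / EI ghost term becomes load +2 F / dx (see b)
    } else {
      for (m in 1:5) add(i, idx[m], st[m])
    }
  }
  b <- numeric(N)
  b[N] <- 2 / dx           # load vector multiplying F(t)
  list(K = c4 * K, b = b, dx = dx)
}

#' Simulate the cantilever driven by a tip force
#'
#' Time-steps the discretized beam equation from rest under the applied
#' tip-force history and returns the tip displacement sampled at the
#' output rate. This is the forward (independent) counterpart of
#' \code{\link{beat_force}}: agreement of the round trip force -> simulated
#' displacement -> reconstructed force is the method's primary
#' verification.
#'
#' @param applied_force A \code{\link{force_trace}} (linearly interpolated
#'   onto the simulation grid), or NULL with \code{y0} for free vibration.
#' @param spec A \code{\link{cantilever}}.
#' @param cfg A \code{\link{beam_sim_config}}.
#' @param y0 Optional initial displacement of the interior nodes (length
#'   \code{n_x}), e.g. a bent shape for free-vibration studies.
#' @return A \code{\link{displacement_trace}} of the tip motion, with
#'   attribute \code{"sim"} recording the config, seed, and the relative
#'   energy-balance error (work input vs. mechanical energy, undamped
#'   runs).
#' @export
simulate_cantilever_fd <- function(applied_force, spec, cfg = beam_sim_config(),
                                   y0 = NULL) {
  stopifnot(inherits(spec, "cantilever"), inherits(cfg, "beam_sim_config"))
  duration <- cfg$duration
  if (is.null(duration)) {
    if (is.null(applied_force))
      stop("'duration' required for free vibration", call. = FALSE)
    duration <- max(applied_force$times) - min(applied_force$times)
  }
  # snap dt so a whole number of steps spans one output frame: the
  # returned trace then sits exactly on the camera grid
  frame <- 1 / cfg$output_fs
  dt <- frame / ceiling(frame / cfg$dt)
  nsteps <- ceiling(duration / dt)
  mats <- .beam_matrices(spec, cfg$n_x)
  N <- cfg$n_x
  K <- mats$K
  rhoA <- spec$density * spec$area
  Cd <- cfg$damping_mass * rhoA * diag(N) + cfg$damping_stiff * K

  # force on the simulation grid
  tgrid <- seq(0, by = dt, length.out = nsteps + 1L)
  if (!is.null(applied_force)) {
    stopifnot(inherits(applied_force, "force_trace"))
    F <- stats::approx(applied_force$times - min(applied_force$times),
                       applied_force$values, xout = tgrid, rule = 2)$y
  } else F <- numeric(nsteps + 1L)

  # Newmark average acceleration: A a1 = b F1 - K ypred - C vpred
  A <- rhoA * diag(N) + (dt / 2) * Cd + (dt^2 / 4) * K
  Ainv <- solve(A)
  y <- if (is.null(y0)) numeric(N) else {
    stopifnot(length(y0) == N); as.numeric(y0)
  }
  v <- numeric(N)
  a <- as.numeric(Ainv %*% (mats$b * F[1L] - K %*% y))
  scale_guard <- max(1e-6, 1e4 * max(abs(F)) / (3 * spec$EI / spec$length^3),
                     1e4 * max(abs(y)))

  keep_every <- max(1L, round(1 / (cfg$output_fs * dt)))
  tip <- numeric(nsteps %/% keep_every + 1L)
  tip_t <- numeric(length(tip))
  tip[1L] <- y[N]; tip_t[1L] <- 0
  kout <- 1L
  work <- 0
  for (s in seq_len(nsteps)) {
    ypred <- y + dt * v + (dt^2 / 4) * a
    vpred <- v + (dt / 2) * a
    a1 <- as.numeric(Ainv %*% (mats$b * F[s + 1L] - K %*% ypred - Cd %*% vpred))
    y1 <- ypred + (dt^2 / 4) * a1
    v1 <- vpred + (dt / 2) * a1
    work <- work + 0.5 * (F[s] * v[N] + F[s + 1L] * v1[N]) * dt
    y <- y1; v <- v1; a <- a1
    if (max(abs(y)) > scale_guard)
      stop("simulation unstable or diverging: reduce 'dt' or check forcing",
           call. = FALSE)
    if (s %% keep_every == 0L) {
      kout <- kout + 1L
      tip[kout] <- y[N]
      tip_t[kout] <- s * dt
    }
  }
  tip <- tip[seq_len(kout)]; tip_t <- tip_t[seq_len(kout)]

  # physical energy audit (trapezoid-weighted quadrature, approximate at
  # the boundaries; a large imbalance signals an inconsistent run)
  dx <- mats$dx
  w <- c(rep(1, N - 1L), 0.5) * dx
  ke <- 0.5 * rhoA * sum(w * v^2)
  ypad <- c(0, y)
  curv <- diff(diff(ypad)) / dx^2
  se <- 0.5 * spec$EI * sum(curv^2) * dx
  ebal <- if (abs(work) > 0) (ke + se - work) / max(abs(work), ke + se) else 0

  out <- displacement_trace(tip_t, tip)
  attr(out, "sim") <- list(config = unclass(cfg), seed = cfg$seed,
                           energy_imbalance = ebal)
  out
}
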