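# Shared fixtures: the default (silver-wire) and compliant probes, and a
# forward-simulated round trip used by several test files.

silver_wire <- cantilever()            # L = 10 mm, d = 0.2 mm
compliant_wire <- compliant_cantilever()  # L = 100 mm, f1 ~ 7.9 Hz

# run twitch -> FD simulation -> (optional noise) -> reconstruction and
# return the fit together with the applied-force truth on the fit grid
fd_round_trip <- function(spec, params, duration, skip, n_x = 50L,
                          dt = 2e-4, noise = NULL, fit_args = list(),
                          damping_stiff = 0) {
  tgrid <- seq(0, duration, by = 1 / 600)
  ft <- twitch_force(params, tgrid, ramp_beats = 2)
  sim <- simulate_cantilever_fd(
    ft, spec, beam_sim_config(n_x = n_x, dt = dt, output_fs = 60,
                              damping_stiff = damping_stiff))
  sel <- sim$times >= skip & sim$times < duration
  tr <- displacement_trace(sim$times[sel], sim$values[sel])
  if (!is.null(noise))
    tr <- add_measurement_noise(tr, noise$pixel_scale, noise$sigma_px,
                                noise$seed)
  fit <- do.call(beat_force, c(list(tr, spec), fit_args))
  truth <- stats::approx(ft$times, ft$values, xout = fit$force$times)$y
  list(fit = fit, truth = truth, applied = ft)
}

rms_rel <- function(x, ref) sqrt(mean((x - ref)^2)) / max(abs(ref))
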