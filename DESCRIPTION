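Package: cantibeat
Title: Cantilever-Probe Beating-Force Reconstruction for Engineered Heart Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the contractile (beating) force that a
    three-dimensional cardiac tissue gel exerts on a thin cantilever probe
    from the probe tip's video-tracked displacement waveform, using the
    transverse forced-oscillation theory of an Euler-Bernoulli cantilever
    (Fourier modal superposition with clamped-end and prescribed-tip
    boundary conditions). Computes per-beat twitch kinetics (peak force,
    20-percent-threshold timing points, contraction and relaxation
    velocities, force-time integral, and their normalized forms) used to
    discriminate atrial-like from ventricular-like beating behaviour.
    Includes an independent finite-difference forward simulator of the
    beam equation, a parametric twitch-force generator with measurement
    noise and synthetic video rendering, sub-pixel template tracking of
    the probe tip, and bioreactor stretch/pulse stimulus timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
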