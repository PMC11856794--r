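# cantibeat

Dynamic beating-force evaluation for engineered heart tissue (EHT) measured
with a thin cantilever probe.

## The problem

A 3D cardiac tissue gel (e.g. hiPS-CM-laden hydrogel) is hooked at one end
to a fixed anchor and at the other to the free end of a thin silver-wire
cantilever (ϕ0.2 mm). Each twitch of the tissue pulls the wire tip; the tip
motion is recorded by a microscope camera at 60 fps. The quantity of
interest — the contractile (beating) force *B(t)* — must be reconstructed
from that displacement waveform.

`cantibeat` does this with the transverse forced-oscillation theory of an
Euler–Bernoulli cantilever rather than a static stiffness extrapolation.
The beam equation

  ρA ∂²y/∂t² = −EI ∂⁴y/∂x⁴

is solved per Fourier harmonic of the measured tip displacement
s(t) = S₀/2 + Σⱼ Sⱼ cos(ωⱼt + φⱼ), with clamped-end conditions
y(0) = y′(0) = 0 and tip conditions y(L) = s(t), y″(L) = 0. The force the
gel exerts is the shear at the hook end,

  B(t) = 3S₀EI/(2L³) + Σⱼ Aⱼ cos(ωⱼt + φⱼ),  Aⱼ = −EI y‴ⱼ(L),

which reduces to the familiar static stiffness 3EI/L³ for slow beating and
corrects for probe inertia when the beating spectrum approaches the probe's
resonances.

From *B(t)* the package computes, per beat, the subtype-discriminating
twitch kinetics: peak force *B*ₘ, the 20 %-threshold times *T*₁, *T*ₘ,
*T*₂, contraction velocity *F*c = 0.8 *B*ₘ/(*T*ₘ−*T*₁), relaxation velocity
*F*r = 0.8 *B*ₘ/(*T*₂−*T*ₘ), the force–time integral *FI* = ∫*B* dt over
[*T*₁, *T*₂], and the normalized forms *F*′c, *F*′r, *FI*′. Atrial-like
beats have larger *F*′c and *F*′r and smaller *FI*′ than ventricular-like
beats; `subtype_shift()` turns two summaries into an ordinal verdict.

Also included: an independent finite-difference forward simulator of the
beam equation (the verification oracle), a parametric twitch generator with
atrial/ventricular presets, camera-noise and synthetic-video models,
sub-pixel tip tracking, and bioreactor stretch/pulse stimulus timelines.

## Worked example

```r
library(cantibeat)

probe <- compliant_cantilever()       # 0.2 mm silver wire, L = 100 mm
tw    <- twitch_params("custom", beat_rate = 0.8,   # 10 uN twitch train,
                       rise_tau = 0.125, decay_tau = 0.225)  # 0.8 Hz
force <- twitch_force(tw, seq(0, 15, by = 1/600), ramp_beats = 2)

# forward oracle: what would the camera see?
sim <- simulate_cantilever_fd(force, probe, beam_sim_config(output_fs = 60))
sel <- sim$times >= 2.5
trace <- displacement_trace(sim$times[sel], sim$values[sel])
trace <- add_measurement_noise(trace, pixel_scale = 2e-6, sigma_px = 0.5,
                               seed = 1)

# inverse: reconstruct the force and summarize the beat kinetics
fit <- beat_force(trace, probe)
summary(fit)
```

```
Beating-force reconstruction (Euler-Bernoulli cantilever inversion)
  probe: L = 100 mm, d = 0.2 mm, EI = 6.519e-06 N m^2
  analysis window: 12.5 s (750 samples at 60 Hz)
  harmonics retained: 198 (dropped energy 8.16e-05)
  static term: 3.424 uN; peak force: 10.17 uN
  dynamic correction vs quasi-static: 17.6%

Beat kinetics over 10 beat(s) (mean +/- SD):
  B_m            10.32 +/- 0.598    uN
  T_1            8.158 +/- 3.79     s
  T_m            8.315 +/- 3.78     s
  T_2            8.818 +/- 3.75     s
  F_c            52.87 +/- 2.93     uN/s
  F_r            16.59 +/- 1.25     uN/s
  FI             4.094 +/- 0.622    uN s
  F_c_norm       5.131 +/- 0.333    1/s
  F_r_norm       1.617 +/- 0.192    1/s
  FI_norm       0.3949 +/- 0.0334   s
```

The reconstruction recovers the 10 µN generator amplitude to ~3 % and the
normalized kinetics to a few percent per run despite pixel quantization
and 0.5 px tracking noise (the generator truth is F′c = 5.16 s⁻¹,
F′r = 1.70 s⁻¹, FI′ = 0.384 s); the static term is the mean contractile
tone, and the 17.6 % dynamic correction shows the inertial terms at work
on this deliberately compliant probe (first natural frequency ≈ 7.9 Hz).
The T₁/Tₘ/T₂ columns are absolute beat times, so their SD across the ten
beats is simply the spread of beat positions in the record.

A thin CLI wrapping the same functions lives at `inst/cli/cantibeat.R`
(subcommands `simulate`, `track`, `reconstruct`, `metrics`, `demo`).

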