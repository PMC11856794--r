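test_that("static calibration force follows 3 EI delta / L^3", {
  cl <- silver_wire
  expect_identical(static_force(0, cl), 0)
  expect_equal(static_force(1e-6, cl), 1.956e-5, tolerance = 1e-3)
  # halving L -> force x8
  half <- cantilever(length = cl$length / 2)
  expect_equal(static_force(1e-6, half) / static_force(1e-6, cl), 8,
               tolerance = 1e-12)
})

test_that("zero displacement reconstructs to zero force", {
  t <- seq(0, 2 - 1 / 60, by = 1 / 60)
  fit <- beat_force(displacement_trace(t, rep(0, length(t))), silver_wire)
  expect_true(all(abs(fit$force$values) < 1e-20))
})

test_that("a held (step-and-hold) displacement reproduces the static force", {
  t <- seq(0, 2 - 1 / 60, by = 1 / 60)
  delta <- 1e-6
  fit <- beat_force(displacement_trace(t, rep(delta, length(t))),
                    silver_wire)
  ref <- static_force(delta, silver_wire)
  expect_equal(fit$force$values, rep(ref, length(t)),
               tolerance = 1e-6 * ref)
  expect_equal(fit$static_term, ref, tolerance = 1e-12)
  # constant trace: quasi-static baseline equals the reconstruction
  qs <- quasistatic_force(displacement_trace(t, rep(delta, length(t))),
                          silver_wire)
  expect_equal(fit$force$values, qs$values, tolerance = 1e-9)
})

test_that("reconstruction is linear in the displacement", {
  t <- seq(0, 5 - 1 / 60, by = 1 / 60)
  s1 <- 1e-6 * cos(2 * pi * 1 * t) + 5e-7
  s2 <- 4e-7 * cos(2 * pi * 2 * t + 0.3)
  args <- list(max_harmonics = 50L, amp_floor = 0, integer_periods = FALSE)
  f1 <- do.call(beat_force,
                c(list(displacement_trace(t, s1), silver_wire), args))
  f2 <- do.call(beat_force,
                c(list(displacement_trace(t, s2), silver_wire), args))
  f12 <- do.call(beat_force,
                 c(list(displacement_trace(t, 2 * s1 - 3 * s2), silver_wire),
                   args))
  expect_equal(f12$force$values,
               2 * f1$force$values - 3 * f2$force$values,
               tolerance = 1e-9 * max(abs(f12$force$values)))
})

test_that("dynamic correction is tiny for stiff and large for compliant probes", {
  t <- seq(0, 4 - 1 / 60, by = 1 / 60)
  s <- 1e-6 * cos(2 * pi * 1 * t)
  fit_stiff <- beat_force(displacement_trace(t, s), silver_wire,
                          integer_periods = FALSE)
  expect_lt(fit_stiff$dynamic_correction, 1e-3)   # f1 ~ 787 Hz
  s5 <- 1e-4 * cos(2 * pi * 5 * t)
  fit_soft <- beat_force(displacement_trace(t, s5), compliant_wire,
                         integer_periods = FALSE)
  expect_gt(fit_soft$dynamic_correction, 0.1)     # f1 ~ 7.9 Hz
})

test_that("forward-inverse round trip recovers the applied twitch force", {
  # headline property at reduced ensemble size; the full 20-waveform
  # sweep runs in the acceptance suite
  rt <- fd_round_trip(silver_wire, twitch_params("ventricular"), 8, 2)
  expect_lt(rms_rel(rt$fit$force$values, rt$truth), 0.03)
  p <- twitch_params("custom", beat_rate = 0.75, rise_tau = 0.16,
                     decay_tau = 0.27)
  rt2 <- fd_round_trip(compliant_wire, p, 12, 4)
  expect_lt(rms_rel(rt2$fit$force$values, rt2$truth), 0.03)
})

test_that("pixel input without a scale and guard violations raise errors", {
  t <- seq(0, 1 - 1 / 60, by = 1 / 60)
  df <- data.frame(time_s = t, displacement_px = sin(2 * pi * t))
  expect_error(beat_force(df, silver_wire), "pixel_scale")
  # a strong harmonic above the guard band on the compliant wire
  s <- 1e-4 * cos(2 * pi * 2 * t) + 1e-4 * cos(2 * pi * 29 * t)
  expect_warning(
    fit <- beat_force(displacement_trace(t, s), compliant_wire,
                      integer_periods = FALSE),
    "guard")
  expect_true(all(fit$force_harmonics$omega < 0.8 * 2 * pi *
                    clamped_pinned_frequency(compliant_wire)))
})

test_that("force CSV round trip is lossless", {
  t <- seq(0, 1 - 1 / 60, by = 1 / 60)
  ft <- force_trace(t, 1e-5 * sin(2 * pi * t))
  path <- withr::local_tempfile(fileext = ".csv")
  write_force(ft, path)
  ft2 <- read_force(path)
  expect_equal(ft2$values, ft$values, tolerance = 1e-12)
})
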