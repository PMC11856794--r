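test_that("displacement_trace enforces the uniform-grid contract", {
  expect_error(displacement_trace(c(0, 1, 1.5), c(0, 0, 0)), "uniform")
  expect_error(displacement_trace(c(0, -1, -2), c(0, 0, 0)), "increasing")
  expect_error(displacement_trace(0:3, c(0, NA, 0, 0)), "finite")
  tr <- displacement_trace(seq(0, 1, by = 1 / 60), rep(0, 61))
  expect_equal(tr$fs, 60, tolerance = 1e-9)
})

test_that("a constant record decomposes to the DC term only", {
  tr <- displacement_trace(seq(0, 1, by = 1 / 60), rep(3e-6, 61))
  dec <- spectral_decompose(tr)
  expect_equal(dec$S0, 6e-6, tolerance = 1e-12)
  expect_equal(nrow(dec$harmonics), 0)
  expect_equal(spectral_reconstruct(dec, c(0, 0.5)), rep(3e-6, 2),
               tolerance = 1e-12)
})

test_that("an integer-period cosine decomposes exactly", {
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  tr <- displacement_trace(t, 5e-6 * cos(2 * pi * 1.0 * t))
  dec <- spectral_decompose(tr, amp_floor = 0)
  expect_lt(abs(dec$S0), 1e-14)
  i1 <- which.max(dec$harmonics$S)
  expect_equal(dec$harmonics$omega[i1] / (2 * pi), 1.0, tolerance = 1e-9)
  expect_equal(dec$harmonics$S[i1], 5e-6, tolerance = 1e-9)
  expect_lt(abs(dec$harmonics$phi[i1]), 1e-9)
  # all other harmonics are numerically zero
  expect_lt(max(dec$harmonics$S[-i1]), 1e-20)
})

test_that("decompose then reconstruct is the identity on band-limited input", {
  set.seed(7)
  t <- seq(0, 5 - 1 / 60, by = 1 / 60)
  x <- 0 * t + 2e-6
  for (j in 1:10)   # integer-period harmonics of 0.2 Hz, below Nyquist
    x <- x + runif(1, 0, 1e-6) * cos(2 * pi * j * 0.2 * t + runif(1, -pi, pi))
  tr <- displacement_trace(t, x)
  dec <- spectral_decompose(tr, max_harmonics = 300L, amp_floor = 0,
                            integer_periods = FALSE)
  expect_lt(max(abs(spectral_reconstruct(dec, t) - x)), 1e-12 * max(abs(x)))
})

test_that("Parseval: retained power + dropped fraction accounts for variance", {
  set.seed(11)
  t <- seq(0, 4 - 1 / 60, by = 1 / 60)
  x <- rnorm(length(t), sd = 1e-6)
  tr <- displacement_trace(t, x)
  dec <- spectral_decompose(tr, max_harmonics = 1000L, amp_floor = 0,
                            integer_periods = FALSE)
  var_tot <- mean((x - mean(x))^2)
  kept <- sum(dec$harmonics$S^2) / 2
  # dropped_energy complements the retained fraction
  expect_equal(kept / var_tot + dec$dropped_energy, 1, tolerance = 1e-9)
  # with every bin retained (odd out: the Nyquist bin), power matches
  nyq_amp <- 2 * Mod(stats::fft(x)[length(x) %/% 2 + 1]) / length(x)
  expect_equal(kept + nyq_amp^2 / 4, var_tot, tolerance = 1e-9)
})

test_that("amplitude floor drops weak harmonics but keeps >= 99% variance", {
  p <- twitch_params("ventricular")
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  ft <- twitch_force(p, t)
  tr <- displacement_trace(t, ft$values / 1e3)   # shape only
  dec <- spectral_decompose(tr, amp_floor = 0.01)
  expect_lt(dec$dropped_energy, 0.01)
  full <- spectral_decompose(tr, amp_floor = 0)
  expect_lt(nrow(dec$harmonics), nrow(full$harmonics))
})

test_that("harmonics above the resonance guard are dropped with a warning", {
  t <- seq(0, 2 - 1 / 60, by = 1 / 60)
  x <- 1e-6 * cos(2 * pi * 2 * t) + 5e-7 * cos(2 * pi * 20 * t)
  tr <- displacement_trace(t, x)
  expect_warning(
    dec <- spectral_decompose(tr, omega_max = 2 * pi * 10,
                              integer_periods = FALSE),
    "guard")
  expect_true(all(dec$harmonics$omega < 2 * pi * 10))
})

test_that("trace CSV round trip is lossless and pixel input needs a scale", {
  t <- seq(0, 1 - 1 / 60, by = 1 / 60)
  tr <- displacement_trace(t, 1e-6 * sin(2 * pi * t))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)
  # pixel dialect
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = t, displacement_px = sin(t)),
                   path2, row.names = FALSE)
  expect_error(read_trace(path2), "pixel_scale")
  tr3 <- read_trace(path2, pixel_scale = 2e-6)
  expect_equal(tr3$values, sin(t) * 2e-6, tolerance = 1e-12)
})
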