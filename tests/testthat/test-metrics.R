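# Closed-form oracle: a triangular pulse rising linearly 0 -> B_m over
# t_rise and falling linearly to 0 over t_fall.  The 20% crossings are at
# 0.2 t_rise and t_rise + 0.8 t_fall; FI is the full triangle area minus
# the two sub-threshold corner triangles.
triangle_truth <- function(B_m, t_rise, t_fall) {
  T_1 <- 0.2 * t_rise
  T_m <- t_rise
  T_2 <- t_rise + 0.8 * t_fall
  FI <- 0.5 * B_m * (t_rise + t_fall) -
    0.5 * 0.2 * B_m * T_1 -              # corner below T_1
    0.5 * 0.2 * B_m * (0.2 * t_fall)     # corner beyond T_2
  list(B_m = B_m, T_1 = T_1, T_m = T_m, T_2 = T_2,
       F_c = 0.8 * B_m / (T_m - T_1), F_r = 0.8 * B_m / (T_2 - T_m),
       FI = FI)
}

triangle_trace <- function(B_m, t_rise, t_fall, fs, pad = 0.1) {
  t <- seq(0, t_rise + t_fall + 2 * pad, by = 1 / fs)
  v <- ifelse(t < pad, 0,
       ifelse(t < pad + t_rise, B_m * (t - pad) / t_rise,
       ifelse(t < pad + t_rise + t_fall,
              B_m * (1 - (t - pad - t_rise) / t_fall), 0)))
  force_trace(t, v)
}

test_that("triangular-pulse kinetics match the closed-form geometry", {
  tru <- triangle_truth(1e-6, 0.2, 0.3)
  # frozen closed-form values
  expect_equal(tru$F_c, 5.0e-6, tolerance = 1e-12)
  expect_equal(tru$F_r, 1e-6 / 0.3, tolerance = 1e-12)
  expect_equal(tru$FI, 0.240e-6, tolerance = 1e-12)

  # dense grid: near-exact agreement
  ftd <- triangle_trace(1e-6, 0.2, 0.3, fs = 2e4)
  md <- beat_parameters(ftd, c(1L, length(ftd$values)),
                        baseline_subtract = FALSE)
  expect_equal(md$F_c, tru$F_c, tolerance = 1e-6)
  expect_equal(md$F_r, tru$F_r, tolerance = 1e-6)
  expect_equal(md$FI, tru$FI, tolerance = 1e-6)
  expect_equal(md$F_c_norm, 5.0, tolerance = 1e-6)
  expect_equal(md$FI_norm, 0.240, tolerance = 1e-6)

  # 60 fps sampling: within 2%
  f60 <- triangle_trace(1e-6, 0.2, 0.3, fs = 60)
  m60 <- beat_parameters(f60, c(1L, length(f60$values)),
                         baseline_subtract = FALSE)
  expect_equal(m60$F_c, tru$F_c, tolerance = 0.02)
  expect_equal(m60$F_r, tru$F_r, tolerance = 0.02)
  expect_equal(m60$FI, tru$FI, tolerance = 0.02)
})

test_that("metric identities and bounds hold by construction", {
  ft <- triangle_trace(2e-6, 0.15, 0.25, fs = 500)
  m <- beat_parameters(ft, c(1L, length(ft$values)))
  expect_true(m$T_1 < m$T_m && m$T_m < m$T_2)
  expect_equal(m$F_c, 0.8 * m$B_m / (m$T_m - m$T_1), tolerance = 1e-12)
  expect_equal(m$F_r, 0.8 * m$B_m / (m$T_2 - m$T_m), tolerance = 1e-12)
  expect_equal(m$F_c_norm, m$F_c / m$B_m, tolerance = 1e-12)
  expect_equal(m$FI_norm, m$FI / m$B_m, tolerance = 1e-12)
  expect_gt(m$FI, 0)
  expect_lt(m$FI, m$B_m * (m$T_2 - m$T_1))   # rectangle bound
})

test_that("kinetics scale correctly under force and time scaling", {
  ft <- triangle_trace(1e-6, 0.2, 0.3, fs = 1000)
  m <- beat_parameters(ft, c(1L, length(ft$values)))
  # force x c: velocities and FI scale, normalized forms unchanged
  ftc <- force_trace(ft$times, 3.7 * ft$values)
  mc <- beat_parameters(ftc, c(1L, length(ftc$values)))
  expect_equal(mc$F_c / m$F_c, 3.7, tolerance = 1e-9)
  expect_equal(mc$FI / m$FI, 3.7, tolerance = 1e-9)
  expect_equal(mc$F_c_norm, m$F_c_norm, tolerance = 1e-9)
  expect_equal(mc$FI_norm, m$FI_norm, tolerance = 1e-9)
  # time x 2: normalized velocities halve, FI' doubles
  ft2 <- force_trace(ft$times * 2, ft$values)
  m2 <- beat_parameters(ft2, c(1L, length(ft2$values)))
  expect_equal(m2$F_c_norm / m$F_c_norm, 0.5, tolerance = 1e-9)
  expect_equal(m2$F_r_norm / m$F_r_norm, 0.5, tolerance = 1e-9)
  expect_equal(m2$FI_norm / m$FI_norm, 2, tolerance = 1e-9)
})

test_that("degenerate beats raise errors naming the failing side", {
  t <- seq(0, 1, by = 0.01)
  # never falls back below threshold
  ft <- force_trace(t, pmin(t, 0.6))
  expect_error(beat_parameters(ft, c(1L, length(t)),
                               baseline_subtract = FALSE), "falling")
})

test_that("beat segmentation finds one window per twitch", {
  p <- twitch_params("ventricular")
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  ft <- twitch_force(p, t)
  win <- segment_beats(ft)
  expect_equal(nrow(win), 10)
  expect_true(all(win$start < win$peak & win$peak <= win$end))
  # windows are disjoint and ordered
  expect_true(all(diff(win$peak) > 0))
  expect_true(all(win$end[-nrow(win)] == win$start[-1]))
})

test_that("constant traces yield no beats, with a warning", {
  ft <- force_trace(seq(0, 1, by = 0.01), rep(1e-6, 101))
  expect_warning(win <- segment_beats(ft), "no qualifying peaks")
  expect_equal(nrow(win), 0)
})

test_that("prominence filtering keeps only the dominant rhythm", {
  t <- seq(0, 10 - 1 / 100, by = 1 / 100)
  # dominant 1 Hz twitches + small 3 Hz ripple
  big <- twitch_force(twitch_params("ventricular"), t)$values
  ripple <- 0.1 * max(big) * (0.5 + 0.5 * sin(2 * pi * 3 * t))
  ft <- force_trace(t, big + ripple)
  win <- segment_beats(ft, min_prominence = 0.2)
  expect_equal(nrow(win), 10)
})

test_that("beat summaries aggregate and subtype_shift orders presets", {
  p <- twitch_params("ventricular")
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  ft <- twitch_force(p, t)
  m <- beat_metrics(ft)
  s <- beat_summary(m)
  expect_equal(unique(s$n), nrow(m))
  # identical beats: SD ~ 0 for all shape parameters (absolute beat times
  # T_1, T_m, T_2 differ across beats by construction)
  shape <- !s$parameter %in% c("T_1", "T_m", "T_2")
  expect_lt(max(s$sd[shape] / pmax(abs(s$mean[shape]), 1e-300)), 1e-6)
  # single-beat summary warns and equals the beat
  expect_warning(s1 <- beat_summary(m[1, ]), "single beat")
  expect_equal(s1$mean[s1$parameter == "B_m"], m$B_m[1])
  expect_true(all(s1$sd == 0))

  # subtype ordering from the generator presets
  fa <- twitch_force(twitch_params("atrial"), t)
  sa <- beat_summary(beat_metrics(fa))
  shift <- subtype_shift(s, sa)       # atrial relative to ventricular
  expect_equal(shift$verdict, "atrial-shifted")
  rev <- subtype_shift(sa, s)
  expect_equal(rev$verdict, "ventricular-shifted")
  same <- subtype_shift(s, s)
  expect_equal(same$verdict, "indeterminate")
  expect_true(all(same$delta == 0))
})
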