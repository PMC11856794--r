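# The modal solution is checked against its own defining boundary
# conditions (direct-substitution oracle) and against static closed forms.

test_that("modal coefficients satisfy all four boundary conditions", {
  cl <- silver_wire
  f_res <- clamped_pinned_frequency(cl)
  set.seed(42)
  for (i in 1:100) {
    S <- runif(1, 1e-8, 1e-4)
    f <- runif(1, 0.01, 0.95 * f_res)   # sub-resonance
    mc <- modal_coefficients(S, 2 * pi * f, runif(1, -pi, pi), cl)
    expect_false(mc$singular)
    # clamped end: y(0) = 0, y'(0) = 0 (scale-relative residuals)
    expect_lt(abs(mode_shape(mc, 0)) / S, 1e-9)
    expect_lt(abs(mode_shape(mc, 0, 1L)) * cl$length / S, 1e-9)
    # tip: y(L) = S, y''(L) = 0
    expect_lt(abs(mode_shape(mc, cl$length) - S) / S, 1e-9)
    expect_lt(abs(mode_shape(mc, cl$length, 2L)) * cl$length^2 / S, 1e-9)
  }
})

test_that("zero-amplitude harmonics give zero coefficients and zero shear", {
  mc <- modal_coefficients(0, 100, 0, silver_wire)
  expect_identical(mc$C1, 0)
  expect_identical(mc$C2, 0)
  expect_identical(tip_shear_amplitude(mc, silver_wire), 0)
})

test_that("tip shear converges to the static point-load closed form", {
  cl <- silver_wire
  S <- 1e-6
  # kappa = 1e-3: quasi-static
  om <- (1e-3 / cl$length)^2 * sqrt(cl$EI / (cl$density * cl$area))
  mc <- modal_coefficients(S, om, 0, cl)
  expect_equal(tip_shear_amplitude(mc, cl), 3 * cl$EI * S / cl$length^3,
               tolerance = 1e-4)
  # ratio to static -> 1 monotonically (from above) as kappa -> 0
  kappas <- c(0.3, 0.2, 0.1, 0.03, 1e-3)
  ratios <- vapply(kappas, function(kap) {
    om <- (kap / cl$length)^2 * sqrt(cl$EI / (cl$density * cl$area))
    m <- modal_coefficients(S, om, 0, cl)
    tip_shear_amplitude(m, cl) / (3 * cl$EI * S / cl$length^3)
  }, numeric(1))
  expect_true(all(diff(abs(ratios - 1)) < 0))
  expect_lt(abs(ratios[length(ratios)] - 1), 1e-4)
})

test_that("modal tip shear agrees with the closed-form transfer function", {
  cl <- compliant_wire
  for (f in c(0.3, 2, 5, 9, 20)) {
    mc <- modal_coefficients(1e-5, 2 * pi * f, 0, cl)
    expect_equal(tip_shear_amplitude(mc, cl),
                 cantibeat:::tip_transfer(2 * pi * f, cl) * 1e-5,
                 tolerance = 1e-10)
  }
})

test_that("resonance roots solve tan(k) = tanh(k) and flag singularity", {
  roots <- resonance_wavenumbers(n = 3L)
  expect_equal(roots[1], 3.9266, tolerance = 1e-4)
  expect_equal(roots[2], 7.0686, tolerance = 1e-4)
  expect_true(all(diff(roots) > 0))
  # determinant vanishes at the roots (relative to its local scale)
  D <- cantibeat:::mode_determinant(roots)
  expect_true(all(abs(D) < 1e-8 * cosh(roots)))
  # determinant has no roots below the first: sign is constant on (0, 3.9)
  kk <- seq(0.01, 3.9, by = 0.01)
  expect_true(all(cantibeat:::mode_determinant(kk) > 0))
  # sign change across each root
  eps <- 1e-3
  for (r in roots)
    expect_lt(cantibeat:::mode_determinant(r - eps) *
                cantibeat:::mode_determinant(r + eps), 0)

  # a harmonic at the resonance is flagged singular and shear errors
  cl <- silver_wire
  om_res <- 2 * pi * clamped_pinned_frequency(cl)
  mc <- suppressWarnings(modal_coefficients(1e-6, om_res, 0, cl))
  expect_true(mc$singular)
  expect_warning(modal_coefficients(1e-6, om_res, 0, cl), "resonance|ill-posed")
  expect_error(tip_shear_amplitude(mc, cl), "resonant")
})
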