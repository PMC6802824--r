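test_that("wavenumber follows k = 2 pi f / c and rejects bad input", {
  expect_equal(wavenumber(120, medium()), 2 * pi * 120000 / 1500,
               tolerance = 1e-12)
  expect_equal(wavenumber(240, medium()) / wavenumber(120, medium()), 2)
  expect_error(wavenumber(0, medium()), "positive")
  expect_error(wavenumber(-10, medium()), "positive")
  expect_error(medium(sound_speed = 0), "positive")
  expect_true(all(diff(ambient_pressure(c(0, 10, 50, 100))) > 0))
  expect_equal(ambient_pressure(30), 101325 * 4)
})

test_that("fluid-like model: zero contrast gives the sentinel, not a crash", {
  sp <- ts_fluid_like(10, fluid_params(1, 1, 10), medium(), c(38, 120))
  expect_true(all(sp$ts == -Inf))
  expect_equal(db_to_linear(sp$ts), c(0, 0))
})

test_that("fluid-like model obeys the Rayleigh f^4 law at small ka", {
  for (shape in c("bent_cylinder", "prolate_spheroid")) {
    p <- fluid_params(1.016, 1.019, 10, 20, 0, shape)
    a <- 13.7e-3 / 10
    f1 <- 0.01 / a * 1500 / (2 * pi) / 1000   # ka = 0.01
    sp <- ts_fluid_like(13.7, p, medium(), c(f1 / 2, f1))
    ratio <- db_to_linear(sp$ts[2]) / db_to_linear(sp$ts[1])
    expect_lt(abs(ratio - 16) / 16, 0.05)
  }
})

test_that("fluid-like model matches the independent quadrature oracle", {
  # single-orientation cases across shapes, contrasts and frequencies
  cases <- expand.grid(len = c(4.26, 13.7), theta = c(0, 20, 45),
                       f = c(38, 120), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- fluid_params(1.016, 1.019, 10, cs$theta, 0, "bent_cylinder")
    got <- db_to_linear(ts_fluid_like(cs$len, p, medium(), cs$f)$ts)
    want <- dwba_sigma_oracle(cs$len, 1.016, 1.019, 10, cs$theta,
                              "bent_cylinder", cs$f)
    expect_lt(abs(10 * log10(got / want)), 0.1)
  }
  # orientation-averaged euphausiid at 120 kHz (reference parameterization)
  p <- fluid_params(1.016, 1.019, 10, 20, 20, "bent_cylinder")
  got <- db_to_linear(ts_fluid_like(13.7, p, medium(), 120)$ts)
  want <- dwba_sigma_oracle_avg(13.7, 1.016, 1.019, 10, 20, 20,
                                "bent_cylinder", 120)
  expect_lt(abs(10 * log10(got / want)), 0.1)
})

test_that("orientation averaging with sd -> 0 equals the single-angle value", {
  p0 <- fluid_params(0.949, 0.995, 5.1, 35, 0, "prolate_spheroid")
  p1 <- fluid_params(0.949, 0.995, 5.1, 35, 1e-7, "prolate_spheroid")
  f <- c(38, 120, 333)
  expect_equal(ts_fluid_like(1.41, p0, medium(), f)$ts,
               ts_fluid_like(1.41, p1, medium(), f)$ts, tolerance = 1e-6)
})

test_that("elastic-shell model has Rayleigh rise and geometric plateau", {
  expect_error(elastic_params(1.2), "0, 1")
  # R = 0: no reflection, sentinel everywhere
  sp0 <- ts_elastic_shell(0.375, elastic_params(0), medium(), c(38, 200))
  expect_true(all(sp0$ts == -Inf))
  # geometric limit at ka = 100
  a <- 0.375e-3
  f_geo <- 100 / a * 1500 / (2 * pi) / 1000
  sp <- ts_elastic_shell(0.375, elastic_params(0.5), medium(), f_geo)
  expect_equal(sp$ts, 10 * log10(a^2 * 0.5^2 / 4), tolerance = 0.1 / abs(sp$ts))
  expect_lt(abs(sp$ts - (-80.56)), 0.1)
  # Rayleigh ratio 16 between ka = 0.01 and 0.02
  f1 <- 0.01 / a * 1500 / (2 * pi) / 1000
  spr <- ts_elastic_shell(0.375, elastic_params(0.5), medium(),
                          c(f1, 2 * f1))
  ratio <- db_to_linear(spr$ts[2]) / db_to_linear(spr$ts[1])
  expect_lt(abs(ratio - 16) / 16, 0.02)
  # monotone non-decreasing in frequency
  g <- seq(10, 420, 2)
  spm <- ts_elastic_shell(0.375, elastic_params(0.5), medium(), g)
  expect_true(all(diff(spm$ts) >= -1e-12))
})

test_that("gas model reduces to the Minnaert sphere in the sphere limit", {
  fine <- seq(2, 30, 0.05)
  sp <- ts_gas_bearing(1.0, gas_params(1, 1e-6, 1e-6), medium(depth = 0),
                       fine)
  pk <- resonance_peak(sp, use_mask = FALSE)
  f0 <- minnaert_f0_khz(0.5e-3)
  expect_lt(abs(pk$frequency - f0) / f0, 0.10)
})

test_that("gas resonance scales with ambient pressure as sqrt(P)", {
  fine <- seq(2, 40, 0.05)
  p <- gas_params(1, 1e-6, 1e-6)
  f_surf <- resonance_peak(ts_gas_bearing(1.0, p, medium(depth = 0), fine),
                           use_mask = FALSE)$frequency
  f_deep <- resonance_peak(ts_gas_bearing(1.0, p, medium(depth = 30), fine),
                           use_mask = FALSE)$frequency
  expect_lt(abs(f_deep / f_surf - 2), 0.05 * 2)
})

test_that("gas model matches the damped Minnaert-sphere oracle (L/2a = 1)", {
  g <- seq(18, 420, 2)
  for (depth in c(0, 83)) {
    for (len in c(0.6, 1.0)) {        # sphere diameter, mm
      med <- medium(depth = depth)
      sp <- ts_gas_bearing(len, gas_params(1, 0.1, 15), med, g)
      want <- vapply(g, function(f)
        minnaert_sphere_sigma_oracle(len * 1e-3 / 2, 0.1, 15, f, med),
        numeric(1))
      expect_lt(max(abs(sp$ts - 10 * log10(want))), 0.2)
    }
  }
})

test_that("siphonophore pneumatophore resonances sit in the reported bands", {
  g <- seq(18, 420, 2)
  p <- gas_params(2.35, 0.1, 15)
  deep <- resonance_peak(ts_gas_bearing(1.23, p, medium(depth = 83), g),
                         use_mask = FALSE)
  expect_gte(deep$frequency, 18)
  expect_lte(deep$frequency, 38)
  surf <- resonance_peak(ts_gas_bearing(0.27, p, medium(depth = 17), g),
                         use_mask = FALSE)
  expect_lte(surf$frequency, 150)
  expect_gte(surf$frequency, 38)
})

test_that("gas peak frequency decreases with size and increases with depth", {
  g <- seq(4, 420, 1)
  p <- gas_params(2.35, 0.01, 1)
  sizes <- c(0.4, 0.8, 1.6, 3.2)
  pk_size <- vapply(sizes, function(L)
    resonance_peak(ts_gas_bearing(L, p, medium(depth = 50), g),
                   use_mask = FALSE)$frequency, numeric(1))
  expect_true(all(diff(pk_size) < 0))
  depths <- c(0, 20, 50, 90)
  pk_depth <- vapply(depths, function(z)
    resonance_peak(ts_gas_bearing(0.8, p, medium(depth = z), g),
                   use_mask = FALSE)$frequency, numeric(1))
  expect_true(all(diff(pk_depth) > 0))
})

test_that("viscous damping lowers the peak and broadens it", {
  g <- seq(10, 420, 0.5)
  med <- medium(depth = 50)
  etas <- c(0.01, 0.1, 0.5, 1)
  pk <- numeric(length(etas)); bw <- numeric(length(etas))
  for (i in seq_along(etas)) {
    sp <- ts_gas_bearing(1.23, gas_params(2.35, etas[i], 15), med, g)
    pk[i] <- resonance_peak(sp, use_mask = FALSE)$value
    bw[i] <- peak_bandwidth(sp, 3)
  }
  expect_true(all(diff(pk) <= 1e-9))
  expect_true(all(diff(bw) >= -1e-9))
})

test_that("every model follows sigma ~ f^4 in the Rayleigh regime", {
  med <- medium()
  # fluid: ka <= 0.01 at the larger frequency
  a <- 13.7e-3 / 10
  f2 <- 0.01 / a * 1500 / (2 * pi) / 1000
  sp <- ts_fluid_like(13.7, fluid_params(1.016, 1.019, 10, 20, 0), med,
                      c(f2 / 2, f2))
  expect_lt(abs(rayleigh_slope(db_to_linear(sp$ts[1]),
                               db_to_linear(sp$ts[2]), f2 / 2, f2) - 4) / 4,
            0.02)
  # elastic
  ae <- 0.375e-3
  fe <- 0.01 / ae * 1500 / (2 * pi) / 1000
  spe <- ts_elastic_shell(0.375, elastic_params(0.5), med, c(fe / 2, fe))
  expect_lt(abs(rayleigh_slope(db_to_linear(spe$ts[1]),
                               db_to_linear(spe$ts[2]), fe / 2, fe) - 4) / 4,
            0.02)
  # gas: far below resonance, ka <= 0.01, adiabatic gas regime (a large
  # enough that the polytropic exponent is flat across the two frequencies)
  spg <- ts_gas_bearing(10, gas_params(1, 0.1, 1e-6), med, c(0.05, 0.1))
  expect_lt(abs(rayleigh_slope(db_to_linear(spg$ts[1]),
                               db_to_linear(spg$ts[2]), 0.05, 0.1) - 4) / 4,
            0.02)
})

test_that("cross-sections are non-negative and masks flag kb >= 0.1", {
  g <- seq(18, 420, 2)
  sp <- ts_gas_bearing(1.23, gas_params(2.35, 0.1, 15), medium(depth = 83),
                       g)
  expect_true(all(db_to_linear(sp$ts) >= 0))
  b <- 1.23e-3 / 2
  expect_equal(sp$mask, wavenumber(g, medium(depth = 83)) * b < 0.1)
  expect_true(any(sp$mask) && any(!sp$mask))
})

test_that("resonance_peak picks the unmasked argmax, ties toward low f", {
  sp <- ts_spectrum(c(10, 20, 30, 40), c(-60, -50, -50, -55))
  pk <- resonance_peak(sp)
  expect_equal(pk$frequency, 20)   # first of the tied maxima
  expect_equal(pk$value, -50)
  mono <- ts_spectrum(1:5, c(-70, -65, -60, -55, -50))
  expect_equal(resonance_peak(mono)$frequency, 5)
  masked <- ts_spectrum(c(10, 20), c(-40, -90), mask = c(FALSE, TRUE))
  expect_equal(resonance_peak(masked)$frequency, 20)
  allmask <- ts_spectrum(c(10, 20), c(-40, -90), mask = c(FALSE, FALSE))
  expect_error(resonance_peak(allmask), "no unmasked")
})

test_that("guarded gas model stays finite even with no viscous damping", {
  fine <- seq(2, 40, 0.01)
  sp <- ts_gas_bearing(1.0, gas_params(1, 0, 0), medium(depth = 0), fine)
  expect_true(all(is.finite(sp$ts)))
})
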