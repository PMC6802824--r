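# Independent oracles, coded from first principles and kept separate from the
# package implementation paths they check.

# DWBA backscattering cross section by adaptive quadrature (stats::integrate
# on real and imaginary parts), parameterized by arc angle for the bent
# cylinder instead of arc length, at a single orientation angle.
dwba_sigma_oracle <- function(length_mm, g, h, length_to_radius, theta_deg,
                              shape = c("bent_cylinder", "prolate_spheroid"),
                              f_khz, med = medium(), curvature_ratio = 3,
                              taper_order = 10) {
  shape <- match.arg(shape)
  L <- length_mm * 1e-3
  a0 <- L / length_to_radius
  k1 <- 2 * pi * f_khz * 1000 / med$sound_speed
  k2 <- k1 / h
  gam <- (1 - g * h^2) / (g * h^2) - (g - 1) / g
  th <- theta_deg * pi / 180
  j1_over <- function(x, cb) {
    # J1(2 k2 a cb)/cb with the end-on limit
    if (length(cb) == 1) cb <- rep(cb, length(x))
    ifelse(abs(cb) < 1e-10, k2 * x,
           besselJ(abs(2 * k2 * x * cb), 1) / abs(cb))
  }
  if (shape == "bent_cylinder") {
    rc <- curvature_ratio * L
    phimax <- L / (2 * rc)
    fn <- function(phi, part) {
      s <- rc * phi
      a_s <- a0 * sqrt(pmax(0, 1 - abs(2 * s / L)^taper_order))
      cb <- cos(th + phi)
      v <- a_s * j1_over(a_s, cb) * exp(-2i * k2 * rc * cos(th + phi)) * rc
      if (part == "re") Re(v) else Im(v)
    }
    re <- stats::integrate(fn, -phimax, phimax, part = "re",
                           subdivisions = 400, rel.tol = 1e-9)$value
    im <- stats::integrate(fn, -phimax, phimax, part = "im",
                           subdivisions = 400, rel.tol = 1e-9)$value
  } else {
    fn <- function(s, part) {
      a_s <- a0 * sqrt(pmax(0, 1 - (2 * s / L)^2))
      cb <- cos(th)
      v <- a_s * j1_over(a_s, cb) * exp(2i * k2 * s * sin(th))
      if (part == "re") Re(v) else Im(v)
    }
    re <- stats::integrate(fn, -L / 2, L / 2, part = "re",
                           subdivisions = 400, rel.tol = 1e-9)$value
    im <- stats::integrate(fn, -L / 2, L / 2, part = "im",
                           subdivisions = 400, rel.tol = 1e-9)$value
  }
  Mod((k1 / 4) * gam * complex(real = re, imaginary = im))^2
}

# Orientation-averaged oracle: dense trapezoid over mean +- 3 SD with
# normal-density weights, averaging sigma in linear scale.
dwba_sigma_oracle_avg <- function(length_mm, g, h, length_to_radius,
                                  mean_deg, sd_deg, shape, f_khz,
                                  med = medium(), n_angle = 241) {
  if (sd_deg <= 0)
    return(dwba_sigma_oracle(length_mm, g, h, length_to_radius, mean_deg,
                             shape, f_khz, med))
  ang <- seq(mean_deg - 3 * sd_deg, mean_deg + 3 * sd_deg,
             length.out = n_angle)
  w <- stats::dnorm(ang, mean_deg, sd_deg)
  w <- w / sum(w)
  sig <- vapply(ang, function(a)
    dwba_sigma_oracle(length_mm, g, h, length_to_radius, a, shape, f_khz,
                      med), numeric(1))
  sum(w * sig)
}

# Damped Minnaert-sphere oracle: resonant gas sphere of the same volume,
# written directly from the bubble formulas (no shape machinery).
minnaert_sphere_sigma_oracle <- function(radius_m, viscosity,
                                         surface_tension, f_khz,
                                         med = medium(), gamma_gas = 1.4) {
  a <- radius_m
  P <- 101325 * (1 + med$depth / 10)
  w <- 2 * pi * f_khz * 1000
  rho_g <- P * 0.0289647 / (8.31446 * med$temperature)
  Dg <- 0.0263 / (rho_g * 1005)
  x <- a * sqrt(w / Dg) * (1 + 1i) / sqrt(2)
  cth <- if (Re(x) > 15) 1 else (exp(2 * x) + 1) / (exp(2 * x) - 1)
  G <- gamma_gas / (1 + 3 * (gamma_gas - 1) * (x * cth - 1) / x^2)
  w0sq <- (3 * G * P + 2 * surface_tension * (3 * gamma_gas - 1) / a) /
    (med$density * a^2)
  k <- w / med$sound_speed
  dd <- abs(Im(w0sq)) / w^2 + k * a +
    4 * viscosity / (med$density * w * a^2)
  a^2 / ((Re(w0sq) / w^2 - 1)^2 + dd^2)
}

minnaert_f0_khz <- function(radius_m, med = medium(), gamma_gas = 1.4) {
  P <- 101325 * (1 + med$depth / 10)
  (1 / (2 * pi * radius_m)) * sqrt(3 * gamma_gas * P / med$density) / 1000
}

# log-log slope of sigma_bs between two frequencies
rayleigh_slope <- function(sigma1, sigma2, f1, f2) {
  (log(sigma2) - log(sigma1)) / (log(f2) - log(f1))
}
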