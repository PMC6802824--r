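#' Parameters for gas-bearing scatterers
#'
#' Shape and damping parameters of the resonant gas prolate-spheroid model
#' used for siphonophore pneumatophores and fish swimbladders. Viscosity and
#' surface tension are effective tissue properties, not those of the gas.
#'
#' @param length_to_width_ratio Spheroid aspect ratio L/2a (semi-major over
#'   semi-minor axis), >= 1.
#' @param viscosity Effective shear viscosity of the surrounding tissue
#'   (Pa s).
#' @param surface_tension Effective surface tension at the gas-tissue
#'   interface (N m-1).
#' @param gas_gamma Heat-capacity ratio of the enclosed gas (air: 1.4).
#' @return An object of class `"gas_params"`.
#' @export
gas_params <- function(length_to_width_ratio, viscosity, surface_tension,
                       gas_gamma = 1.4) {
  if (length_to_width_ratio < 1) stop("'length_to_width_ratio' must be >= 1")
  if (viscosity < 0) stop("'viscosity' must be non-negative")
  if (surface_tension < 0) stop("'surface_tension' must be non-negative")
  if (gas_gamma <= 1) stop("'gas_gamma' must exceed 1")
  structure(list(length_to_width_ratio = length_to_width_ratio,
                 viscosity = viscosity, surface_tension = surface_tension,
                 gas_gamma = gas_gamma),
            class = "gas_params")
}

# Air properties for the enclosed gas (ideal gas at ambient pressure).
.air <- list(molar_mass = 0.0289647,   # kg/mol
             gas_constant = 8.31446,   # J/(mol K)
             conductivity = 0.0263,    # W/(m K)
             heat_capacity = 1005)     # J/(kg K), c_p

# Electrostatic capacitance of a prolate spheroid with semi-axes a < b;
# equals the radius for a sphere. Drives the shape correction of the
# breathing-mode resonance (Strasberg's equivalent-capacitance result).
spheroid_capacitance <- function(a, b) {
  if (b <= a * (1 + 1e-9)) return((a * a * b)^(1 / 3))
  cc <- sqrt(b^2 - a^2)
  2 * cc / log((b + cc) / (b - cc))
}

# Complex coth, stable for large real part.
coth_c <- function(z) {
  out <- rep(1 + 0i, length(z))
  small <- Re(z) <= 15
  e <- exp(2 * z[small])
  out[small] <- (e + 1) / (e - 1)
  out
}

#' Gas-bearing target strength (damped resonant prolate spheroid)
#'
#' Backscattering of a gas-filled prolate spheroid (pneumatophore or
#' swimbladder) as a damped monopole resonator. The resonance frequency is
#' the Minnaert frequency of the equal-volume sphere, modified by
#' (i) the prolate-shape (capacitance) correction, (ii) surface-tension
#' stiffening `2*tau*(3*gamma - 1)/a_eq`, and (iii) the complex polytropic
#' exponent of the enclosed gas, whose imaginary part supplies thermal
#' damping. Radiation damping (`k a_eq`) and viscous damping
#' (`4 eta / (rho omega a_eq^2)`) complete the total damping, so the
#' cross section
#' \deqn{\sigma_{bs}(f) = \frac{a_{eq}^2}
#'   {\left(f_0^2/f^2 - 1\right)^2 + \delta^2}}
#' is finite everywhere, including at exact resonance.
#'
#' The model is a Rayleigh-regime approximation: the validity mask flags
#' frequencies where `k * b >= 0.1` (with `b` the semi-major axis, the
#' binding constraint since `a < b`). Out-of-validity values are still
#' computed and returned.
#'
#' @param length Length of the gas inclusion (mm); the semi-major axis is
#'   `length / 2` and the semi-minor axis `length / 2 / (L/2a)`.
#' @param params A [gas_params()] object.
#' @param medium A [medium()] object (depth sets the ambient pressure).
#' @param frequencies Frequency grid (kHz).
#' @return A [ts_spectrum()] with validity mask.
#' @examples
#' sp <- ts_gas_bearing(1.23, gas_params(2.35, 0.1, 15),
#'                      medium(depth = 83), seq(18, 420, 2))
#' resonance_peak(sp)
#' @export
ts_gas_bearing <- function(length, params, medium = sslspectra::medium(),
                           frequencies) {
  stopifnot(inherits(params, "gas_params"))
  if (length <= 0) stop("'length' must be positive (mm)")
  b <- length * 1e-3 / 2
  a <- b / params$length_to_width_ratio
  aeq <- (a * a * b)^(1 / 3)
  P <- medium$ambient_pressure
  rho <- medium$density
  gam <- params$gas_gamma
  omega <- 2 * pi * frequencies * 1000
  k <- wavenumber(frequencies, medium)

  # thermal behaviour of the enclosed gas: complex polytropic exponent
  rho_gas <- P * .air$molar_mass / (.air$gas_constant * medium$temperature)
  D_gas <- .air$conductivity / (rho_gas * .air$heat_capacity)
  chi <- aeq * sqrt(omega / D_gas) * complex(real = 1, imaginary = 1) / sqrt(2)
  Gamma_c <- gam / (1 + 3 * (gam - 1) * (chi * coth_c(chi) - 1) / chi^2)

  shape2 <- spheroid_capacitance(a, b) / aeq   # multiplies omega_0^2
  stiffness <- 3 * Gamma_c * P +
    2 * params$surface_tension * (3 * gam - 1) / aeq
  Omega2 <- shape2 * stiffness / (rho * aeq^2)  # complex "resonance" term

  H_re <- Re(Omega2) / omega^2 - 1
  delta <- abs(Im(Omega2)) / omega^2 +                      # thermal
    k * aeq +                                               # radiation
    4 * params$viscosity / (rho * omega * aeq^2)            # viscous
  sigma <- aeq^2 / (H_re^2 + pmax(delta, 1e-12)^2)
  ts_spectrum(frequencies, linear_to_db(sigma), mask = (k * b) < 0.1)
}
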