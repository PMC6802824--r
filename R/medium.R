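#' Acoustic medium description
#'
#' Bundles the seawater properties needed by the scattering models. Ambient
#' pressure is derived from depth with the usual 1-atm-per-10-m hydrostatic
#' rule, and the temperature is that of the gas inside inclusions (used for
#' the thermal damping of gas bubbles, not for the sound speed, which is
#' given directly).
#'
#' @param sound_speed Sound speed in seawater (m s-1).
#' @param density Seawater density (kg m-3).
#' @param depth Depth of the scatterers (m); drives ambient pressure.
#' @param temperature Absolute temperature (K) of the gas in inclusions.
#' @return An object of class `"medium"`: a list with fields `sound_speed`,
#'   `density`, `depth`, `temperature` and the derived `ambient_pressure` (Pa).
#' @examples
#' medium(depth = 83)
#' @export
medium <- function(sound_speed = 1500, density = 1026, depth = 0,
                   temperature = 283.15) {
  if (!is.numeric(sound_speed) || length(sound_speed) != 1 || sound_speed <= 0)
    stop("'sound_speed' must be a single positive number (m/s)")
  if (!is.numeric(density) || length(density) != 1 || density <= 0)
    stop("'density' must be a single positive number (kg/m^3)")
  if (!is.numeric(depth) || length(depth) != 1 || depth < 0)
    stop("'depth' must be a single non-negative number (m)")
  if (temperature <= 0)
    stop("'temperature' must be positive (K)")
  structure(
    list(sound_speed = sound_speed, density = density, depth = depth,
         temperature = temperature,
         ambient_pressure = ambient_pressure(depth)),
    class = "medium")
}

#' Hydrostatic ambient pressure
#'
#' One atmosphere at the surface plus one atmosphere per 10 m of depth:
#' `P(z) = 101325 * (1 + z / 10)` Pa.
#'
#' @param depth Depth (m), non-negative.
#' @return Ambient pressure (Pa).
#' @export
ambient_pressure <- function(depth) {
  if (any(depth < 0)) stop("'depth' must be non-negative")
  101325 * (1 + depth / 10)
}

#' Acoustic wavenumber
#'
#' `k = 2 * pi * f / c` with `f` converted from kHz to Hz.
#'
#' @param frequency Acoustic frequency or frequencies (kHz), strictly positive.
#' @param medium A [medium()] object.
#' @return Wavenumber(s) in m-1.
#' @examples
#' wavenumber(120, medium())  # ~502.65
#' @export
wavenumber <- function(frequency, medium = sslspectra::medium()) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency <= 0))
    stop("'frequency' must be positive and finite (kHz)")
  2 * pi * frequency * 1000 / medium$sound_speed
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf(
    "Acoustic medium: c = %g m/s, rho = %g kg/m^3, depth = %g m (P = %g kPa)\n",
    x$sound_speed, x$density, x$depth, x$ambient_pressure / 1000))
  invisible(x)
}
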