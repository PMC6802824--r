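#' Parameters for elastic-shell scatterers
#'
#' The high-pass dense-fluid sphere model for hard-shelled pteropods is
#' driven by a single empirically derived reflection coefficient.
#'
#' @param R Reflection coefficient in `[0, 1]` (default 0.5, the empirical
#'   value for thecosome pteropods).
#' @return An object of class `"elastic_params"`.
#' @export
elastic_params <- function(R = 0.5) {
  if (!is.numeric(R) || length(R) != 1 || R < 0 || R > 1)
    stop("'R' must be a single number in [0, 1]")
  structure(list(R = R), class = "elastic_params")
}

#' Elastic-shell target strength (high-pass dense-fluid sphere)
#'
#' Rayleigh \eqn{(ka)^4} rise at low frequency, saturating at the geometric
#' limit \eqn{\sigma_{bs} = a^2 R^2 / 4} at high frequency:
#' \deqn{\sigma_{bs} = \frac{R^2}{4} a^2 \frac{(ka)^4}{1 + (ka)^4}.}
#' Monotone non-decreasing in frequency.
#'
#' @param equivalent_radius Radius (mm) of the sphere with the same silhouette
#'   area as the organism (see [radius_from_silhouette()]).
#' @param params An [elastic_params()] object.
#' @param medium A [medium()] object.
#' @param frequencies Frequency grid (kHz).
#' @return A [ts_spectrum()]. `R = 0` yields the zero-backscatter sentinel.
#' @export
ts_elastic_shell <- function(equivalent_radius, params = elastic_params(),
                             medium = sslspectra::medium(), frequencies) {
  stopifnot(inherits(params, "elastic_params"))
  if (equivalent_radius <= 0) stop("'equivalent_radius' must be positive (mm)")
  a <- equivalent_radius * 1e-3
  ka <- wavenumber(frequencies, medium) * a
  sigma <- (params$R^2 / 4) * a^2 * ka^4 / (1 + ka^4)
  ts_spectrum(frequencies, linear_to_db(sigma))
}
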