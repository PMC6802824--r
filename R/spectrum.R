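#' Decibel / linear conversions
#'
#' Backscatter is aggregated in natural (linear) scale and reported in dB.
#' The zero-backscatter sentinel is `-Inf` dB, which these helpers map to an
#' exact linear 0 and back, so sums in linear scale treat it as nothing.
#'
#' @param db Values in dB.
#' @return `db_to_linear`: linear-scale values; `linear_to_db`: dB values.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' @rdname db_to_linear
#' @param x Linear-scale values (non-negative).
#' @export
linear_to_db <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("linear backscatter must be non-negative")
  out <- rep(-Inf, length(x))
  pos <- is.finite(x) & x > 0
  out[pos] <- 10 * log10(x[pos])
  out[is.na(x)] <- NA_real_
  out
}

new_spectrum <- function(frequencies, values, mask, field, class) {
  if (!is.numeric(frequencies) || length(frequencies) < 1)
    stop("'frequencies' must be a non-empty numeric vector (kHz)")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("'frequencies' must be strictly increasing")
  if (length(values) != length(frequencies))
    stop(sprintf("'%s' and 'frequencies' lengths differ", field))
  if (is.null(mask)) mask <- rep(TRUE, length(frequencies))
  if (!is.logical(mask) || length(mask) != length(frequencies))
    stop("'mask' must be a logical vector matching 'frequencies'")
  out <- list(frequencies = as.numeric(frequencies),
              values = as.numeric(values),
              mask = mask)
  names(out)[2] <- field
  structure(out, class = c(class, "acoustic_spectrum"))
}

#' Target-strength spectrum
#'
#' A TS spectrum on a masked frequency grid. `mask` flags the frequencies at
#' which the generating model is considered valid; out-of-validity values are
#' still stored. `-Inf` dB is the zero-backscatter sentinel.
#'
#' @param frequencies Strictly increasing frequency grid (kHz).
#' @param ts Target strength per frequency (dB re 1 m^2).
#' @param mask Logical validity flag per frequency (default all `TRUE`).
#' @return An object of class `"ts_spectrum"`.
#' @export
ts_spectrum <- function(frequencies, ts, mask = NULL) {
  new_spectrum(frequencies, ts, mask, "ts", "ts_spectrum")
}

#' Volume-backscattering spectrum
#'
#' An Sv spectrum (dB re 1 m-1) on a masked frequency grid, with the same
#' grid conventions as [ts_spectrum()].
#'
#' @inheritParams ts_spectrum
#' @param sv Volume backscattering strength per frequency (dB re 1 m-1).
#' @return An object of class `"sv_spectrum"`.
#' @export
sv_spectrum <- function(frequencies, sv, mask = NULL) {
  new_spectrum(frequencies, sv, mask, "sv", "sv_spectrum")
}

spectrum_values <- function(x) {
  if (inherits(x, "ts_spectrum")) x$ts else x$sv
}

is_sentinel_spectrum <- function(x) all(spectrum_values(x) == -Inf)

check_common_grid <- function(a, b) {
  if (length(a$frequencies) != length(b$frequencies) ||
      any(abs(a$frequencies - b$frequencies) > 1e-9))
    stop("spectra are not on a common frequency grid")
  invisible(TRUE)
}

#' Locate the resonance (maximum) of a spectrum
#'
#' Returns the frequency and level of the spectrum maximum over unmasked
#' frequencies; ties are broken toward the lowest frequency. Used to locate
#' the resonance peaks of gas-bearing scatterers.
#'
#' @param spectrum A [ts_spectrum()] or [sv_spectrum()].
#' @param use_mask If `TRUE` (default) only unmasked frequencies are searched.
#' @return A list with `frequency` (kHz) and `value` (dB).
#' @export
resonance_peak <- function(spectrum, use_mask = TRUE) {
  stopifnot(inherits(spectrum, "acoustic_spectrum"))
  keep <- if (use_mask) spectrum$mask else rep(TRUE, length(spectrum$mask))
  if (!any(keep)) stop("no unmasked frequencies: spectrum has no peak")
  v <- spectrum_values(spectrum)
  f <- spectrum$frequencies
  i <- which(keep)[which.max(v[keep])]  # which.max takes the first maximum
  list(frequency = f[i], value = v[i])
}

#' Width of a spectral peak at a given drop from its maximum
#'
#' @param spectrum A spectrum object.
#' @param drop_db Level drop defining the band edges (default 3 dB).
#' @return Bandwidth in kHz (distance between the outermost grid frequencies
#'   within `drop_db` of the peak).
#' @export
peak_bandwidth <- function(spectrum, drop_db = 3) {
  v <- spectrum_values(spectrum)
  keep <- which(v >= max(v) - drop_db)
  diff(range(spectrum$frequencies[keep]))
}

#' @export
print.ts_spectrum <- function(x, ...) {
  cat(sprintf("TS spectrum: %d frequencies (%g-%g kHz), %d masked\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              sum(!x$mask)))
  invisible(x)
}

#' @export
print.sv_spectrum <- function(x, ...) {
  cat(sprintf("Sv spectrum: %d frequencies (%g-%g kHz), %d masked\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              sum(!x$mask)))
  invisible(x)
}

#' @export
plot.acoustic_spectrum <- function(x, ..., ylab = NULL) {
  v <- spectrum_values(x)
  if (is.null(ylab))
    ylab <- if (inherits(x, "ts_spectrum")) "TS (dB re 1 m2)" else
      "Sv (dB re 1 m-1)"
  graphics::plot(x$frequencies, v, type = "l", xlab = "Frequency (kHz)",
                 ylab = ylab, ...)
  if (any(!x$mask))
    graphics::points(x$frequencies[!x$mask], v[!x$mask], pch = 4,
                     col = "grey60")
  invisible(x)
}
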