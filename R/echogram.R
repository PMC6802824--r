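#' Echogram grid of per-cell Sv spectra
#'
#' Container for echo-integrated broadband data: a regular grid of
#' echo-integration cells (ping block x depth bin), each carrying an Sv
#' spectrum on a common frequency grid. The conventional cell geometry is
#' 1.5 m vertically by 5 pings horizontally; depth bins are half-open
#' `[top, top + depth_bin)` and data shallower than the first bin top are
#' assumed already discarded.
#'
#' @param sv 3-D numeric array, `ping_block x depth_bin x frequency`
#'   (dB re 1 m-1; `-Inf` is the zero-backscatter sentinel).
#' @param frequencies Strictly increasing frequency grid (kHz).
#' @param depth_top0 Depth of the top of the shallowest bin (m, default 10).
#' @param depth_bin Vertical bin size (m, default 1.5).
#' @param freq_mask Logical usable-frequency mask (default from
#'   [grid_mask()] with the default bands).
#' @return An object of class `"echogram_grid"`.
#' @export
echogram_grid <- function(sv, frequencies, depth_top0 = 10, depth_bin = 1.5,
                          freq_mask = NULL) {
  if (length(dim(sv)) != 3)
    stop("'sv' must be a 3-D array: ping_block x depth_bin x frequency")
  if (dim(sv)[3] != length(frequencies))
    stop("third dimension of 'sv' must match 'frequencies'")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("'frequencies' must be strictly increasing")
  if (is.null(freq_mask)) freq_mask <- grid_mask(frequencies)
  if (length(freq_mask) != length(frequencies))
    stop("'freq_mask' must match 'frequencies'")
  structure(list(sv = sv, frequencies = as.numeric(frequencies),
                 freq_mask = freq_mask,
                 depth_tops = depth_top0 + (seq_len(dim(sv)[2]) - 1) * depth_bin,
                 depth_bin = depth_bin,
                 n_ping = dim(sv)[1], n_depth = dim(sv)[2]),
            class = "echogram_grid")
}

#' @export
print.echogram_grid <- function(x, ...) {
  cat(sprintf(
    "Echogram grid: %d ping blocks x %d depth bins (%g-%g m), %d frequencies\n",
    x$n_ping, x$n_depth, min(x$depth_tops),
    max(x$depth_tops) + x$depth_bin, length(x$frequencies)))
  invisible(x)
}

#' Cell spectra as a matrix
#'
#' Flattens the grid to a cells-by-frequency matrix. Cells are ordered ping
#' fastest (column-major over ping block then depth bin).
#'
#' @param grid An [echogram_grid()].
#' @return Numeric matrix `(n_ping * n_depth) x n_freq`.
#' @export
cell_matrix <- function(grid) {
  stopifnot(inherits(grid, "echogram_grid"))
  matrix(grid$sv, nrow = grid$n_ping * grid$n_depth,
         ncol = length(grid$frequencies))
}

cell_spectrum <- function(grid, ping, depth_idx) {
  sv_spectrum(grid$frequencies, grid$sv[ping, depth_idx, ],
              mask = grid$freq_mask)
}

#' Linear band mean of an Sv spectrum
#'
#' Mean of `10^(Sv/10)` over the unmasked bins of one transducer band
#' (the per-band term of the spectrum-standardization denominator).
#'
#' @param spectrum An [sv_spectrum()].
#' @param f_min,f_max Band boundaries (kHz, inclusive).
#' @return Linear mean sv; `NA` with a warning if the band is fully masked.
#' @export
band_mean_sv <- function(spectrum, f_min, f_max) {
  inband <- spectrum$frequencies >= f_min & spectrum$frequencies <= f_max &
    spectrum$mask
  if (!any(inband)) {
    warning(sprintf("band %g-%g kHz fully masked; excluded", f_min, f_max))
    return(NA_real_)
  }
  mean(db_to_linear(spectrum_values(spectrum)[inband]))
}

#' Standardize an Sv spectrum by its bandwidth-weighted mean
#'
#' Subtracts the dB value of the mean of the per-transducer linear band
#' means:
#' \deqn{S_v^{std}(f) = S_v(f) - 10\log_{10}\left(
#'   \frac{1}{N}\sum_{n=1}^{N} \overline{sv}_n\right).}
#' The result is invariant to a uniform dB offset of the input. A sentinel
#' (all `-Inf`) spectrum is passed through unchanged.
#'
#' @param spectrum An [sv_spectrum()].
#' @param bands A [transducer_bands()] object.
#' @return A standardized [sv_spectrum()] (dB, zero-mean in the band sense).
#' @export
standardize_spectrum <- function(spectrum, bands = transducer_bands()) {
  stopifnot(inherits(spectrum, "sv_spectrum"))
  if (is_sentinel_spectrum(spectrum)) return(spectrum)
  bm <- vapply(seq_len(nrow(bands$table)), function(i)
    suppressWarnings(band_mean_sv(spectrum, bands$table$f_min[i],
                                  bands$table$f_max[i])),
    numeric(1))
  usable <- !is.na(bm)
  if (!any(usable)) stop("no usable transducer band in spectrum")
  scalar <- mean(bm[usable])
  if (scalar <= 0)
    return(spectrum)  # zero-backscatter sentinel passthrough
  sv_spectrum(spectrum$frequencies, spectrum$sv - 10 * log10(scalar),
              mask = spectrum$mask)
}

#' Standardized cell features for clustering
#'
#' Standardizes every cell spectrum ([standardize_spectrum()]) and keeps the
#' frequencies used as the clustering feature space: unmasked bins of all
#' bands except those listed in `bands$cluster_exclude`, optionally dropping
#' the CW (narrowband) points.
#'
#' @param grid An [echogram_grid()].
#' @param bands A [transducer_bands()] object.
#' @param include_cw Keep the CW band points as features (default `TRUE`).
#' @return List with `features` (cells x kept-frequency matrix) and
#'   `frequencies` (the kept frequencies).
#' @export
cluster_features <- function(grid, bands = transducer_bands(),
                             include_cw = TRUE) {
  m <- cell_matrix(grid)
  std <- t(apply(m, 1, function(row)
    standardize_spectrum(sv_spectrum(grid$frequencies, row,
                                     mask = grid$freq_mask), bands)$sv))
  bnames <- band_of(grid$frequencies, bands)
  keep <- grid$freq_mask & !is.na(bnames) &
    !(bnames %in% bands$cluster_exclude)
  if (!include_cw) {
    kinds <- bands$table$kind[match(bnames, bands$table$name)]
    keep <- keep & kinds != "CW"
  }
  list(features = std[, keep, drop = FALSE],
       frequencies = grid$frequencies[keep])
}
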