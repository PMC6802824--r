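#' Net-tow track through an echogram
#'
#' A sequence of (ping block, headline depth) points describing where a
#' sampling net traveled through the echogram grid.
#'
#' @param ping_block Integer ping-block indices.
#' @param headline_depth_m Depth of the net headline (top of the net mouth)
#'   at each ping block (m).
#' @param gear Gear label (default `""`).
#' @return An object of class `"net_track"` (a data.frame).
#' @export
net_track <- function(ping_block, headline_depth_m, gear = "") {
  if (length(ping_block) != length(headline_depth_m))
    stop("'ping_block' and 'headline_depth_m' lengths differ")
  structure(data.frame(ping_block = as.integer(ping_block),
                       headline_depth_m = as.numeric(headline_depth_m),
                       gear = gear, stringsAsFactors = FALSE),
            class = c("net_track", "data.frame"))
}

track_cells <- function(grid, track, n_cells = 2) {
  bad <- track$ping_block < 1 | track$ping_block > grid$n_ping
  sel <- lapply(seq_len(nrow(track)), function(i) {
    if (bad[i]) return(NULL)
    below <- which(grid$depth_tops >= track$headline_depth_m[i] - 1e-9)
    if (length(below) < n_cells) {
      bad[i] <<- TRUE
      return(NULL)
    }
    cbind(ping = track$ping_block[i], depth = below[seq_len(n_cells)])
  })
  if (any(bad))
    stop("track points outside the grid (rows ",
         paste(which(bad), collapse = ", "), ")")
  do.call(rbind, sel)
}

#' Measured Sv spectrum along a net track
#'
#' Extracts, for every track point, the `n_cells` echo-integration cells
#' located below the top of the net (the bins whose tops lie at or below the
#' headline depth), and returns the per-frequency median Sv in the dB domain
#' with 25/75% quantile bands.
#'
#' @param grid An [echogram_grid()].
#' @param track A [net_track()] fully inside the grid (points outside raise
#'   an error listing the offending rows).
#' @param n_cells Cells taken below the headline at each point (default 2).
#' @param domain `"db"` (default: quantiles of the dB values, the plotting
#'   convention) or `"linear"` (quantiles of linear sv, then converted).
#' @return List with `spectrum` (the median, an [sv_spectrum()]), `q25`,
#'   `q75` (dB vectors) and `n_cells_used`.
#' @export
track_measured_sv <- function(grid, track, n_cells = 2,
                              domain = c("db", "linear")) {
  domain <- match.arg(domain)
  stopifnot(inherits(grid, "echogram_grid"), inherits(track, "net_track"))
  cells <- track_cells(grid, track, n_cells)
  m <- t(vapply(seq_len(nrow(cells)), function(i)
    grid$sv[cells[i, "ping"], cells[i, "depth"], ],
    numeric(length(grid$frequencies))))
  if (domain == "linear") m <- db_to_linear(m)
  qs <- apply(m, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  if (domain == "linear") qs <- matrix(linear_to_db(qs), nrow = 3)
  list(spectrum = sv_spectrum(grid$frequencies, qs[2, ],
                              mask = grid$freq_mask),
       q25 = qs[1, ], q75 = qs[3, ], n_cells_used = nrow(cells))
}

#' Compare predicted and measured Sv spectra
#'
#' Per-frequency discrepancy (predicted minus measured, dB) plus mean
#' discrepancies over named frequency intervals and the narrowband-equivalent
#' points used for cross-checking against conventional multi-frequency
#' surveys.
#'
#' @param predicted,measured [sv_spectrum()] objects on a common grid.
#' @param intervals Named list of `c(f_min, f_max)` kHz intervals (default:
#'   the whole band).
#' @param narrowband Frequencies (kHz) at which point differences are
#'   reported (nearest grid frequency; default 18, 38, 70, 120, 200, 333).
#' @return List with `diff` (an [sv_spectrum()] of differences),
#'   `interval_summary` (data.frame: interval, f_min, f_max, mean_diff_db)
#'   and `narrowband` (data.frame: frequency, grid_frequency, diff_db).
#' @export
compare_spectra <- function(predicted, measured, intervals = NULL,
                            narrowband = c(18, 38, 70, 120, 200, 333)) {
  stopifnot(inherits(predicted, "sv_spectrum"),
            inherits(measured, "sv_spectrum"))
  check_common_grid(predicted, measured)
  f <- predicted$frequencies
  d <- predicted$sv - measured$sv
  mask <- predicted$mask & measured$mask
  if (is.null(intervals))
    intervals <- list(full_band = range(f))
  isum <- do.call(rbind, lapply(names(intervals), function(nm) {
    iv <- intervals[[nm]]
    keep <- f >= iv[1] & f <= iv[2] & mask & is.finite(d)
    data.frame(interval = nm, f_min = iv[1], f_max = iv[2],
               mean_diff_db = if (any(keep)) mean(d[keep]) else NA_real_)
  }))
  nb <- do.call(rbind, lapply(narrowband, function(fq) {
    i <- which.min(abs(f - fq))
    data.frame(frequency = fq, grid_frequency = f[i], diff_db = d[i])
  }))
  list(diff = sv_spectrum(f, d, mask = mask), interval_summary = isum,
       narrowband = nb)
}
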