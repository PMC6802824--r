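#' Read / write sample-record tables
#'
#' CSV with header columns `taxon`, `model_class`, `layer`, `length_mm`,
#' `density_ind_m3`, `source` (UTF-8). Validation errors name the offending
#' row. An empty file with a header yields an empty record table.
#'
#' @param path CSV path.
#' @return `read_samples`: a validated [sample_records()] table;
#'   `write_samples`: `path`, invisibly.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("taxon", "model_class", "layer", "source"),
                        names(df)))
    df[[col]] <- as.character(df[[col]])
  req <- c("taxon", "model_class", "length_mm", "density_ind_m3")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) {
    df$layer <- character(0); df$source <- character(0)
    class(df) <- c("sample_records", "data.frame")
    return(df)
  }
  for (col in c("length_mm", "density_ind_m3")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: row %d: non-numeric %s '%s'", path, bad[1], col,
                   df[[col]][bad[1]]))
    df[[col]] <- v
  }
  validate_records(df)
}

#' @rdname read_samples
#' @param records A [sample_records()] table.
#' @export
write_samples <- function(records, path) {
  records <- validate_records(as.data.frame(records))
  cols <- c("taxon", "model_class", "layer", "length_mm", "density_ind_m3",
            "source")
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read / write echogram grids as flat CSV
#'
#' The dialect is one row per echo-integration cell: `ping_block`,
#' `depth_top`, then one `sv_<frequency>` column per grid frequency
#' (full-precision dB values; `-Inf` is preserved). A leading `#mask:`
#' comment line records the usable-frequency mask, making the round trip
#' lossless.
#'
#' @param grid An [echogram_grid()].
#' @param path CSV path.
#' @return `write_grid`: `path` invisibly; `read_grid`: an
#'   [echogram_grid()].
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "echogram_grid"))
  f <- grid$frequencies
  m <- cell_matrix(grid)
  df <- data.frame(ping_block = rep(seq_len(grid$n_ping), grid$n_depth),
                   depth_top = rep(grid$depth_tops, each = grid$n_ping))
  # 17 significant digits so float64 values round-trip bit-identically
  svdf <- as.data.frame(lapply(seq_len(ncol(m)), function(j)
    ifelse(is.finite(m[, j]), sprintf("%.17g", m[, j]),
           as.character(m[, j]))))
  names(svdf) <- sprintf("sv_%g", f)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mask: ", paste(as.integer(grid$freq_mask),
                                     collapse = ",")), con)
  utils::write.csv(cbind(df, svdf), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @param expected_frequencies Optional frequency grid to validate against;
#'   mismatches raise an error listing the offending frequencies.
#' @export
read_grid <- function(path, expected_frequencies = NULL) {
  first <- readLines(path, n = 1)
  has_mask <- startsWith(first, "#mask:")
  df <- utils::read.csv(path, skip = if (has_mask) 1 else 0,
                        check.names = FALSE)
  svcols <- grep("^sv_", names(df), value = TRUE)
  f <- as.numeric(sub("^sv_", "", svcols))
  if (!is.null(expected_frequencies)) {
    extra <- setdiff(f, expected_frequencies)
    miss <- setdiff(expected_frequencies, f)
    if (length(extra) || length(miss))
      stop("grid frequencies do not match the configured bands; offending: ",
           paste(c(extra, miss), collapse = ", "))
  }
  mask <- if (has_mask)
    as.logical(as.integer(strsplit(sub("^#mask: *", "", first),
                                   ",")[[1]]))
  else NULL
  pings <- sort(unique(df$ping_block))
  depths <- sort(unique(df$depth_top))
  depth_bin <- if (length(depths) > 1) min(diff(depths)) else 1.5
  sv <- array(NA_real_, c(length(pings), length(depths), length(f)))
  pi_ <- match(df$ping_block, pings)
  di <- match(df$depth_top, depths)
  for (j in seq_along(svcols))
    sv[cbind(pi_, di, j)] <- df[[svcols[j]]]
  echogram_grid(sv, f, depth_top0 = depths[1], depth_bin = depth_bin,
                freq_mask = mask)
}

#' Write a layer prediction to CSV
#'
#' One row per frequency: the total Sv, one column per taxon component, and
#' the validity mask.
#'
#' @param prediction A [predict_layer()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, path) {
  stopifnot(inherits(prediction, "layer_prediction"))
  df <- data.frame(frequency_khz = prediction$frequencies,
                   sv_total = prediction$total$sv)
  for (tx in names(prediction$taxon_sv))
    df[[paste0("sv_", tx)]] <- prediction$taxon_sv[[tx]]$sv
  df$mask <- as.integer(prediction$total$mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write net tracks
#'
#' CSV with columns `ping_block`, `headline_depth_m` (and optional `gear`).
#'
#' @param path CSV path.
#' @return `read_track`: a [net_track()]; `write_track`: `path`, invisibly.
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path)
  net_track(df$ping_block, df$headline_depth_m,
            gear = if ("gear" %in% names(df)) df$gear[1] else "")
}

#' @rdname read_track
#' @param track A [net_track()].
#' @export
write_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
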