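MODEL_CLASSES <- c("fluid_like_cylinder", "fluid_like_spheroid",
                   "elastic_shell", "gas_bearing", "excluded")

#' Biological sample records
#'
#' Builds and validates the sample table that feeds the forward model: one
#' row per measured organism (or per length draw), with its taxon, scattering
#' model class, length and the density it represents.
#'
#' @param taxon Taxon label.
#' @param model_class One of `r paste(MODEL_CLASSES, collapse = ", ")`.
#' @param length_mm Length (mm): body length, pneumatophore length or
#'   swimbladder length, depending on the taxon convention in the
#'   configuration.
#' @param density_ind_m3 Density represented by the record (ind m-3).
#' @param layer Layer label (default `""`).
#' @param source Sampling gear / method tag (default `""`).
#' @return A validated `data.frame` of class `"sample_records"`.
#' @export
sample_records <- function(taxon, model_class, length_mm, density_ind_m3,
                           layer = "", source = "") {
  df <- data.frame(taxon = as.character(taxon),
                   model_class = as.character(model_class),
                   layer = as.character(layer),
                   length_mm = as.numeric(length_mm),
                   density_ind_m3 = as.numeric(density_ind_m3),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_records(df)
}

#' @rdname sample_records
#' @param records A data frame with the columns above.
#' @export
validate_records <- function(records) {
  req <- c("taxon", "model_class", "length_mm", "density_ind_m3")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("missing sample-record columns: ", paste(missing_cols, collapse = ", "))
  if (!"layer" %in% names(records)) records$layer <- ""
  if (!"source" %in% names(records)) records$source <- ""
  bad <- which(!records$model_class %in% MODEL_CLASSES)
  if (length(bad))
    stop(sprintf("row %d: unknown model_class '%s'", bad[1],
                 records$model_class[bad[1]]))
  bad <- which(!is.finite(records$length_mm) | records$length_mm <= 0)
  if (length(bad))
    stop(sprintf("row %d: length_mm must be a positive number", bad[1]))
  bad <- which(!is.finite(records$density_ind_m3) | records$density_ind_m3 < 0)
  if (length(bad))
    stop(sprintf("row %d: density_ind_m3 must be non-negative", bad[1]))
  class(records) <- c("sample_records", "data.frame")
  records
}

#' Bin sample records into length classes
#'
#' Assigns every record to a half-open length bin (lower edge inclusive) of
#' the given width, per taxon and model class, summing densities. Density
#' mass is conserved exactly; the representative length of each bin is the
#' density-weighted mean length of its records.
#'
#' @param records A [sample_records()] table.
#' @param bin_width Bin width (mm), positive (default 0.1).
#' @return A `data.frame` with columns `taxon`, `model_class`, `bin_lower`,
#'   `bin_upper`, `length_mm` (representative), `density_ind_m3`. Empty input
#'   gives an empty table.
#' @export
bin_samples <- function(records, bin_width = 0.1) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  records <- validate_records(as.data.frame(records))
  if (nrow(records) == 0)
    return(data.frame(taxon = character(), model_class = character(),
                      bin_lower = numeric(), bin_upper = numeric(),
                      length_mm = numeric(), density_ind_m3 = numeric()))
  idx <- floor(records$length_mm / bin_width + 1e-9)
  key <- paste(records$taxon, records$model_class, idx, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(rows) {
    d <- records$density_ind_m3[rows]
    len <- records$length_mm[rows]
    wmean <- if (sum(d) > 0) sum(len * d) / sum(d) else mean(len)
    data.frame(taxon = records$taxon[rows[1]],
               model_class = records$model_class[rows[1]],
               bin_lower = idx[rows[1]] * bin_width,
               bin_upper = (idx[rows[1]] + 1) * bin_width,
               length_mm = wmean,
               density_ind_m3 = sum(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$taxon, out$model_class, out$bin_lower), ]
  rownames(out) <- NULL
  out
}

#' Taxon-level Sv from per-bin TS and densities
#'
#' Aggregates the TS spectra of a taxon's length classes into its volume
#' backscattering spectrum:
#' \deqn{S_{vj}(f) = 10 \log_{10} \sum_i 10^{(TS_i(f) + 10\log_{10} D_i)/10}.}
#' Bins with zero density contribute nothing.
#'
#' @param ts_list List of [ts_spectrum()] objects, one per length class, on a
#'   common frequency grid.
#' @param densities Densities `D_i` (ind m-3), one per spectrum.
#' @return An [sv_spectrum()]; its mask is the AND of the component masks.
#' @export
sv_taxon <- function(ts_list, densities) {
  if (length(ts_list) != length(densities))
    stop("one density is required per TS spectrum")
  if (length(ts_list) == 0) stop("empty TS list")
  f <- ts_list[[1]]$frequencies
  for (s in ts_list) check_common_grid(ts_list[[1]], s)
  lin <- vapply(ts_list, function(s) db_to_linear(s$ts), numeric(length(f)))
  total <- as.vector(lin %*% densities)
  mask <- Reduce(`&`, lapply(ts_list, `[[`, "mask"))
  sv_spectrum(f, linear_to_db(total), mask = mask)
}

#' Total Sv from taxon components
#'
#' Natural-scale (linear) sum of per-taxon Sv spectra:
#' \deqn{S_v(f) = 10 \log_{10} \sum_j 10^{S_{vj}(f)/10}.}
#'
#' @param components List of [sv_spectrum()] objects on a common grid.
#' @param frequencies Frequency grid used for the sentinel output when
#'   `components` is empty.
#' @return An [sv_spectrum()].
#' @export
sv_total <- function(components, frequencies = NULL) {
  if (length(components) == 0) {
    if (is.null(frequencies))
      stop("'frequencies' is required for an empty component list")
    return(sv_spectrum(frequencies, rep(-Inf, length(frequencies))))
  }
  f <- components[[1]]$frequencies
  for (s in components) check_common_grid(components[[1]], s)
  lin <- rowSums(vapply(components, function(s) db_to_linear(s$sv),
                        numeric(length(f))))
  mask <- Reduce(`&`, lapply(components, `[[`, "mask"))
  sv_spectrum(f, linear_to_db(lin), mask = mask)
}

ts_for_bin <- function(entry, length_mm, medium, frequencies, config) {
  cls <- entry$class
  if (cls %in% c("fluid_like_cylinder", "fluid_like_spheroid")) {
    p <- fluid_params(
      g = entry$g, h = entry$h,
      length_to_radius = 2 * entry$length_to_width_ratio,
      orientation_mean = entry$orientation_mean,
      orientation_sd = entry$orientation_sd,
      shape = if (cls == "fluid_like_cylinder") "bent_cylinder"
              else "prolate_spheroid")
    return(ts_fluid_like(length_mm, p, medium, frequencies))
  }
  if (cls == "elastic_shell") {
    frac <- if (is.null(entry$radius_fraction)) 0.5 else entry$radius_fraction
    return(ts_elastic_shell(length_mm * frac, elastic_params(entry$R),
                            medium, frequencies))
  }
  if (cls == "gas_bearing") {
    p <- gas_params(entry$length_to_width_ratio, entry$viscosity,
                    entry$surface_tension)
    gas_len <- if (identical(entry$length_is, "body")) {
      swimbladder_dims(length_mm, entry$length_to_width_ratio)$length
    } else length_mm
    return(ts_gas_bearing(gas_len, p, medium, frequencies))
  }
  stop("cannot compute TS for model class: ", cls)
}

#' Forward-predict the Sv spectrum of one layer
#'
#' Full forward pipeline for one depth layer: bin the sample records into
#' length classes, compute a TS spectrum per class with the scattering model
#' configured for each taxon, aggregate per taxon, and sum taxa in linear
#' scale into the layer total. Records with model class `"excluded"` are
#' carried through but never enter the prediction.
#'
#' @param records A [sample_records()] table for the layer.
#' @param medium A [medium()] object; its depth drives the ambient pressure
#'   seen by gas-bearing scatterers (use the layer depth midpoint).
#' @param frequencies Frequency grid (kHz).
#' @param config Configuration (default [default_config()]).
#' @param bin_width Length-class width (mm); defaults to the configured value.
#' @return An object of class `"layer_prediction"`: list with `total`
#'   ([sv_spectrum()]), `taxon_sv` (named list of [sv_spectrum()]),
#'   `frequencies`, `medium`, and `binned` (the length-class table used).
#' @export
predict_layer <- function(records, medium = sslspectra::medium(),
                          frequencies, config = default_config(),
                          bin_width = config$bin_width) {
  records <- validate_records(as.data.frame(records))
  active <- records[records$model_class != "excluded", , drop = FALSE]
  binned <- bin_samples(active, bin_width)
  taxa <- unique(binned$taxon)
  taxon_sv <- list()
  for (tx in taxa) {
    rows <- binned[binned$taxon == tx, , drop = FALSE]
    entry <- resolve_model(config, tx, rows$model_class[1])
    if (entry$class == "excluded") next
    occupied <- rows$density_ind_m3 > 0
    if (!any(occupied)) next
    rows <- rows[occupied, , drop = FALSE]
    ts_list <- lapply(rows$length_mm, function(len)
      ts_for_bin(entry, len, medium, frequencies, config))
    taxon_sv[[tx]] <- sv_taxon(ts_list, rows$density_ind_m3)
  }
  structure(list(total = sv_total(taxon_sv, frequencies),
                 taxon_sv = taxon_sv,
                 frequencies = frequencies, medium = medium, binned = binned),
            class = "layer_prediction")
}

#' @export
print.layer_prediction <- function(x, ...) {
  cat(sprintf("Layer prediction: %d taxa, %d frequencies (%g-%g kHz)\n",
              length(x$taxon_sv), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  for (tx in names(x$taxon_sv)) {
    pk <- resonance_peak(x$taxon_sv[[tx]], use_mask = FALSE)
    cat(sprintf("  %-30s max Sv %7.2f dB at %g kHz\n", tx, pk$value,
                pk$frequency))
  }
  invisible(x)
}

#' Per-taxon attribution fractions
#'
#' Linear-scale share of each taxon in the layer total at every frequency;
#' the shares sum to 1 wherever the total is non-zero.
#'
#' @param prediction A [predict_layer()] result.
#' @return Matrix (frequency x taxon) of linear fractions.
#' @export
attribution_fractions <- function(prediction) {
  stopifnot(inherits(prediction, "layer_prediction"))
  lin <- vapply(prediction$taxon_sv, function(s) db_to_linear(s$sv),
                numeric(length(prediction$frequencies)))
  tot <- rowSums(lin)
  sweep(lin, 1, ifelse(tot > 0, tot, 1), "/")
}
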