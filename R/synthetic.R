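#' Layer specification for the synthetic-data generator
#'
#' Describes one vertically bounded scattering layer: its depth range, its
#' community (taxa with mean/SD lengths and densities) and the per-cell dB
#' noise level of the echogram cells it generates.
#'
#' @param name Layer label.
#' @param depth_range `c(top, bottom)` depth range (m).
#' @param taxa `data.frame` with columns `taxon`, `model_class`,
#'   `mean_length`, `sd_length` (mm) and `density` (ind m-3).
#' @param noise_sd SD of the additive, independent normal noise applied to
#'   each cell value in the dB domain (default 2).
#' @return An object of class `"layer_spec"`.
#' @export
layer_spec <- function(name, depth_range, taxa, noise_sd = 2) {
  stopifnot(length(depth_range) == 2, depth_range[1] < depth_range[2])
  req <- c("taxon", "model_class", "mean_length", "sd_length", "density")
  if (!all(req %in% names(taxa)))
    stop("'taxa' must have columns: ", paste(req, collapse = ", "))
  if (any(taxa$density < 0)) stop("densities must be non-negative")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(name = name, depth_range = depth_range, taxa = taxa,
                 noise_sd = noise_sd),
            class = "layer_spec")
}

#' Preset communities
#'
#' Springtime Bay-of-Biscay community presets for a near-surface layer
#' (10-24 m, at the thermocline) and a deep layer (70-96 m): euphausiids,
#' *Limacina* pteropods, copepods, physonect-siphonophore pneumatophores,
#' fish, and the weak scatterers (jellyfish, comb jellies, swimming crabs)
#' that are carried in the tables but excluded from predictions. Lengths are
#' body lengths except for pneumatophores and swimbladdered fish, where the
#' gas inclusion itself is measured.
#'
#' The single swimbladdered fish caught near the surface is retained in the
#' table but flagged `excluded` (one individual is not a density estimate).
#'
#' @param noise_sd Per-cell echogram noise SD (dB) carried by the layer spec.
#' @return A [layer_spec()].
#' @export
surface_layer_spec <- function(noise_sd = 2) {
  layer_spec("surface", c(10, 24), data.frame(
    taxon = c("euphausiids", "limacina", "copepods",
              "swimbladdered_fish", "siphonophore_pneumatophore",
              "jellyfish"),
    model_class = c("fluid_like_cylinder", "elastic_shell",
                    "fluid_like_spheroid", "excluded", "gas_bearing",
                    "excluded"),
    mean_length = c(4.26, 0.75, 1.28, 1.53, 0.27, 30.1),
    sd_length = c(2.22, 0.12, 0.37, 0, 0.11, 10),
    density = c(14.2, 5358, 1403, 0, 8.32, 0.033),
    stringsAsFactors = FALSE), noise_sd = noise_sd)
}

#' @rdname surface_layer_spec
#' @export
deep_layer_spec <- function(noise_sd = 2) {
  layer_spec("deep", c(70, 96), data.frame(
    taxon = c("euphausiids", "limacina", "copepods", "swimbladdered_fish",
              "argentina_sphyranea", "siphonophore_pneumatophore",
              "jellyfish", "swimming_crabs", "comb_jelly"),
    model_class = c("fluid_like_cylinder", "elastic_shell",
                    "fluid_like_spheroid", "gas_bearing",
                    "fluid_like_cylinder", "gas_bearing", "excluded",
                    "excluded", "excluded"),
    mean_length = c(13.7, 0.71, 1.41, 0.52, 21.5, 1.23, 24.47, 31.75, 13.6),
    sd_length = c(9.15, 0.15, 0.52, 0.15, 3.89, 0.31, 13.38, 3.54, 7),
    density = c(1.53, 126, 126, 0.0065, 0.012, 0.48, 0.006, 0.0015, 0.0022),
    stringsAsFactors = FALSE), noise_sd = noise_sd)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Draw a sample-record community from a layer specification
#'
#' For each taxon, draws `n_per_taxon` lengths from a normal distribution
#' truncated at 0.05 mm and splits the taxon density evenly across records,
#' so the total density is conserved exactly.
#'
#' @param spec A [layer_spec()].
#' @param n_per_taxon Records per taxon (>= 1, default 100).
#' @param seed Integer seed.
#' @return A [sample_records()] table.
#' @export
make_community <- function(spec, n_per_taxon = 100, seed) {
  stopifnot(inherits(spec, "layer_spec"), n_per_taxon >= 1)
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  recs <- lapply(seq_len(nrow(spec$taxa)), function(i) {
    tx <- spec$taxa[i, ]
    lens <- rnorm_trunc(n_per_taxon, tx$mean_length, tx$sd_length, 0.05)
    data.frame(taxon = tx$taxon, model_class = tx$model_class,
               layer = spec$name, length_mm = lens,
               density_ind_m3 = tx$density / n_per_taxon,
               source = "synthetic", stringsAsFactors = FALSE)
  })
  validate_records(do.call(rbind, recs))
}

#' Simulate a layered echogram with known ground truth
#'
#' Builds a synthetic echogram emulating vertically stratified scattering
#' layers: for each layer, a community is drawn ([make_community()]) and its
#' noiseless Sv spectrum forward-predicted at the layer's depth midpoint
#' ([predict_layer()]); each cell then receives the layer spectrum plus
#' independent normal dB noise. Layers must tile the depth extent without
#' overlap.
#'
#' @param layers List of [layer_spec()] objects with non-overlapping,
#'   contiguous depth ranges.
#' @param frequencies Frequency grid (kHz).
#' @param n_ping_blocks Number of ping blocks (default 40).
#' @param depth_bin Vertical bin (m, default 1.5).
#' @param seed Integer seed (all randomness derives from it).
#' @param config Configuration (default [default_config()]).
#' @param n_per_taxon Community records per taxon (default 100).
#' @param layer_spectra Optional named list of precomputed noiseless layer
#'   [sv_spectrum()]s (keyed by layer name) to reuse across noise settings.
#' @return List with `grid` (an [echogram_grid()]) and `truth` (class
#'   `"ssl_ground_truth"`: `labels` ping x depth matrix of layer indices,
#'   `layer_spectra`, `communities`, `layers`, `seed`).
#' @export
make_layered_echogram <- function(layers, frequencies, n_ping_blocks = 40,
                                  depth_bin = 1.5, seed,
                                  config = default_config(),
                                  n_per_taxon = 100, layer_spectra = NULL) {
  stopifnot(length(layers) >= 1)
  if (missing(seed)) stop("'seed' is required")
  tops <- vapply(layers, function(l) l$depth_range[1], numeric(1))
  o <- order(tops)
  layers <- layers[o]
  rng <- t(vapply(layers, `[[`, numeric(2), "depth_range"))
  if (any(rng[-1, 1] < rng[-nrow(rng), 2] - 1e-9))
    stop("layer depth ranges overlap")
  if (any(abs(rng[-1, 1] - rng[-nrow(rng), 2]) > 1e-9))
    stop("layer depth ranges must be contiguous")
  top0 <- rng[1, 1]
  n_depth <- round((rng[nrow(rng), 2] - top0) / depth_bin)
  if (n_depth < length(layers))
    stop("depth extent too small for the requested bins")
  depth_tops <- top0 + (seq_len(n_depth) - 1) * depth_bin
  lab_depth <- vapply(depth_tops, function(d)
    max(which(rng[, 1] <= d + 1e-9)), integer(1))

  communities <- list()
  spectra <- list()
  for (i in seq_along(layers)) {
    ls <- layers[[i]]
    communities[[ls$name]] <- make_community(ls, n_per_taxon,
                                             seed = seed + i)
    if (!is.null(layer_spectra) && !is.null(layer_spectra[[ls$name]])) {
      spectra[[ls$name]] <- layer_spectra[[ls$name]]
    } else {
      med <- medium(sound_speed = config$medium$sound_speed,
                    density = config$medium$density,
                    depth = mean(ls$depth_range),
                    temperature = config$medium$temperature)
      spectra[[ls$name]] <- predict_layer(communities[[ls$name]], med,
                                          frequencies, config)$total
    }
  }

  set.seed(seed)
  nf <- length(frequencies)
  sv <- array(NA_real_, c(n_ping_blocks, n_depth, nf))
  for (j in seq_len(n_depth)) {
    li <- lab_depth[j]
    base <- spectra[[layers[[li]]$name]]$sv
    noise <- matrix(stats::rnorm(n_ping_blocks * nf, 0,
                                 layers[[li]]$noise_sd),
                    n_ping_blocks, nf)
    if (layers[[li]]$noise_sd == 0) noise[] <- 0
    sv[, j, ] <- matrix(base, n_ping_blocks, nf, byrow = TRUE) + noise
  }
  grid <- echogram_grid(sv, frequencies, depth_top0 = top0,
                        depth_bin = depth_bin,
                        freq_mask = grid_mask(frequencies,
                                              transducer_bands(config)))
  truth <- structure(
    list(labels = matrix(rep(lab_depth, each = n_ping_blocks),
                         n_ping_blocks, n_depth),
         layer_spectra = spectra, communities = communities,
         layers = layers, seed = seed),
    class = "ssl_ground_truth")
  list(grid = grid, truth = truth)
}

#' Synthetic net track through a simulated layer
#'
#' Builds a tow trajectory for [track_measured_sv()]: either a flat tow
#' along the top of one layer (so the two cells below the headline stay
#' inside it), or a W-shaped tow sweeping the full depth extent across
#' several layers, emulating an oblique haul.
#'
#' @param grid An [echogram_grid()] from [make_layered_echogram()].
#' @param truth The matching ground truth.
#' @param layer_name Layer to sample (ignored for `shape = "W"`).
#' @param shape `"flat"` or `"W"`.
#' @return A [net_track()] spanning all ping blocks (at least 10 are
#'   required).
#' @export
make_net_track <- function(grid, truth, layer_name = NULL,
                           shape = c("flat", "W")) {
  shape <- match.arg(shape)
  if (grid$n_ping < 10)
    stop("the grid must span at least 10 ping blocks")
  pings <- seq_len(grid$n_ping)
  if (shape == "flat") {
    idx <- which(vapply(truth$layers, `[[`, character(1), "name") ==
                   layer_name)
    if (!length(idx)) stop("unknown layer: ", layer_name)
    rng <- truth$layers[[idx]]$depth_range
    if (diff(rng) < 2 * grid$depth_bin)
      stop("layer thinner than two echo-integration cells")
    depth <- rep(rng[1], grid$n_ping)
  } else {
    lo <- min(grid$depth_tops)
    hi <- max(grid$depth_tops) - grid$depth_bin  # room for 2 cells below
    phase <- ((pings - 1) %% ceiling(grid$n_ping / 4)) /
      ceiling(grid$n_ping / 4)
    depth <- lo + (hi - lo) * abs(2 * phase - 1)
  }
  net_track(pings, depth, gear = paste0("synthetic_", shape))
}
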