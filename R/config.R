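#' Default run configuration
#'
#' Nested list of every constant the pipeline needs: the medium, the
#' transducer band table, per-taxon scattering-model parameters, the prior
#' distributions used by the uncertainty analysis, and pipeline defaults
#' (length-bin width, layer depth midpoints). Values are the literature
#' parameterization for a springtime Bay-of-Biscay mesozooplankton /
#' micronekton community; every field can be overridden, and the whole
#' structure round-trips through YAML via [read_config()] / [write_config()].
#'
#' Model entries are keyed by a normalized taxon name (lower case,
#' underscores). Each entry carries `class` (one of `fluid_like_cylinder`,
#' `fluid_like_spheroid`, `elastic_shell`, `gas_bearing`, `excluded`) plus
#' the class-specific parameters. For gas-bearing entries, `length_is`
#' states whether the recorded length is the gas inclusion itself
#' (`"gas_inclusion"`: pneumatophores, directly measured swimbladders) or
#' the fish body (`"body"`: the swimbladder is then derived with
#' [swimbladder_dims()]).
#'
#' @return A named list of class `"ssl_config"`.
#' @export
default_config <- function() {
  cfg <- list(
    medium = list(sound_speed = 1500, density = 1026, temperature = 283.15),
    bin_width = 0.1,
    layer_depth = list(surface = 17, deep = 83),
    bands = list(
      list(name = "ES18",  f_min = 18,  f_max = 18,  kind = "CW"),
      list(name = "ES38",  f_min = 38,  f_max = 38,  kind = "CW"),
      list(name = "ES70",  f_min = 47,  f_max = 90,  kind = "FM"),
      list(name = "ES120", f_min = 95,  f_max = 160, kind = "FM"),
      list(name = "ES200", f_min = 180, f_max = 240, kind = "FM"),
      list(name = "ES333", f_min = 280, f_max = 420, kind = "FM")),
    exclusions = list(c(240, 260)),
    cluster_exclude_bands = "ES333",
    models = list(
      euphausiids = list(class = "fluid_like_cylinder", g = 1.016, h = 1.019,
                         length_to_width_ratio = 5,
                         orientation_mean = 20, orientation_sd = 20),
      decapod_shrimp = list(class = "fluid_like_cylinder", g = 1.016,
                            h = 1.019, length_to_width_ratio = 5,
                            orientation_mean = 20, orientation_sd = 20),
      copepods = list(class = "fluid_like_spheroid", g = 0.949, h = 0.995,
                      length_to_width_ratio = 2.55,
                      orientation_mean = 90, orientation_sd = 30),
      fish_without_swimbladder = list(class = "fluid_like_cylinder", g = 1.01,
                                      h = 1.025, length_to_width_ratio = 4,
                                      orientation_mean = 0,
                                      orientation_sd = 30),
      argentina_sphyranea = list(class = "fluid_like_cylinder", g = 1.01,
                                 h = 1.025, length_to_width_ratio = 4,
                                 orientation_mean = 0, orientation_sd = 30),
      pteropods = list(class = "elastic_shell", R = 0.5,
                       radius_fraction = 0.5),
      limacina = list(class = "elastic_shell", R = 0.5,
                      radius_fraction = 0.5),
      siphonophore_pneumatophore = list(class = "gas_bearing",
                                        length_is = "gas_inclusion",
                                        length_to_width_ratio = 2.35,
                                        viscosity = 0.1,
                                        surface_tension = 15),
      swimbladdered_fish = list(class = "gas_bearing",
                                length_is = "gas_inclusion",
                                length_to_width_ratio = 1.63,
                                viscosity = 1, surface_tension = 200),
      crystallogobius_linearis = list(class = "gas_bearing",
                                      length_is = "gas_inclusion",
                                      length_to_width_ratio = 1.63,
                                      viscosity = 1, surface_tension = 200),
      carapus_acus = list(class = "gas_bearing",
                          length_is = "gas_inclusion",
                          length_to_width_ratio = 2.75,
                          viscosity = 1, surface_tension = 200),
      other_swimbladdered_fish = list(class = "gas_bearing",
                                      length_is = "body",
                                      length_to_width_ratio = 1.5,
                                      viscosity = 1, surface_tension = 200),
      jellyfish = list(class = "excluded"),
      comb_jelly = list(class = "excluded"),
      swimming_crabs = list(class = "excluded")),
    # re-run switch: model swimbladderless fish as gas-bearing instead of
    # fluid-like (their swimbladder development stage being uncertain)
    fish_no_swimbladder_as_gas = FALSE,
    priors = list(
      siphonophore = list(
        length_to_width_ratio = list(kind = "normal", mu = 2.35, sd = 0.3),
        viscosity = list(kind = "lognormal", mu = -2.3, sd = 1),
        surface_tension = list(kind = "lognormal", mu = 2.7, sd = 1)),
      swimbladdered_fish = list(
        length_to_width_ratio = list(kind = "normal", mu = NA, sd = 0.2),
        viscosity = list(kind = "lognormal", mu = 0, sd = 1),
        surface_tension = list(kind = "lognormal", mu = 5.3, sd = 1)),
      copepods = list(
        length_to_radius = list(kind = "normal", mu = 5.5, sd = 1),
        g = list(kind = "normal", mu = 0.96, sd = 0.0075),
        h = list(kind = "normal", mu = 0.99, sd = 0.0075)),
      euphausiids = list(
        length_to_radius = list(kind = "normal", mu = 10, sd = 1.5),
        g = list(kind = "normal", mu = 1.016, sd = 0.0075),
        h = list(kind = "normal", mu = 1.019, sd = 0.0075)),
      fish_without_swimbladder = list(
        length_to_radius = list(kind = "normal", mu = 8, sd = 1.5),
        g = list(kind = "normal", mu = 1.01, sd = 0.0075),
        h = list(kind = "normal", mu = 1.025, sd = 0.0075)),
      pteropods = list(
        R = list(kind = "lognormal", mu = -0.69, sd = 0.4))))
  structure(cfg, class = c("ssl_config", "list"))
}

normalize_taxon <- function(x) {
  gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
}

#' Resolve the scattering-model entry for a taxon
#'
#' Looks the (normalized) taxon name up in `config$models`; if absent, falls
#' back on the record's `model_class` using neutral class defaults. A taxon
#' that is neither configured nor carries a usable `model_class` is a hard
#' error: records are never silently dropped.
#'
#' @param config An [default_config()]-style list.
#' @param taxon Taxon label.
#' @param model_class Model class carried by the sample record (or `NA`).
#' @return The model entry (a list with at least `class`).
#' @export
resolve_model <- function(config, taxon, model_class = NA) {
  key <- normalize_taxon(taxon)
  entry <- config$models[[key]]
  if (!is.null(entry)) {
    if (!is.na(model_class) && model_class != entry$class &&
        model_class != "excluded")
      stop(sprintf("taxon '%s': record model_class '%s' conflicts with configured class '%s'",
                   taxon, model_class, entry$class))
    return(entry)
  }
  if (is.na(model_class) || !nzchar(model_class))
    stop(sprintf("taxon '%s' is not configured and carries no model_class", taxon))
  defaults <- list(
    fluid_like_cylinder = config$models$euphausiids,
    fluid_like_spheroid = config$models$copepods,
    elastic_shell = config$models$pteropods,
    gas_bearing = config$models$siphonophore_pneumatophore,
    excluded = list(class = "excluded"))
  entry <- defaults[[model_class]]
  if (is.null(entry))
    stop(sprintf("taxon '%s': unknown model_class '%s'", taxon, model_class))
  entry$class <- model_class
  entry
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config`: an `"ssl_config"` list; `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml flattens length-2 numeric vectors; restore exclusion intervals
  cfg$exclusions <- lapply(cfg$exclusions, as.numeric)
  structure(cfg, class = c("ssl_config", "list"))
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Transducer band table
#'
#' Assembles the band definitions of a configuration into a data frame plus
#' exclusion intervals, the form consumed by the standardization and
#' clustering functions.
#'
#' @param config A configuration list (default [default_config()]).
#' @return An object of class `"transducer_bands"`: list with `table`
#'   (data.frame: name, f_min, f_max, kind), `exclusions` (list of kHz
#'   intervals) and `cluster_exclude` (band names left out of the clustering
#'   feature space).
#' @export
transducer_bands <- function(config = default_config()) {
  tab <- do.call(rbind, lapply(config$bands, function(b)
    data.frame(name = b$name, f_min = b$f_min, f_max = b$f_max,
               kind = b$kind, stringsAsFactors = FALSE)))
  if (any(tab$f_min > tab$f_max)) stop("band with f_min > f_max")
  o <- order(tab$f_min)
  tab <- tab[o, , drop = FALSE]
  if (any(tab$f_max[-nrow(tab)] > tab$f_min[-1]))
    stop("transducer bands must not overlap")
  structure(list(table = tab, exclusions = config$exclusions,
                 cluster_exclude = config$cluster_exclude_bands),
            class = "transducer_bands")
}

#' Frequency grid spanned by the transducer bands
#'
#' CW bands contribute their single frequency; FM bands a regular grid at
#' `step` kHz. Frequencies inside exclusion intervals are kept on the grid
#' but flagged unusable by [grid_mask()].
#'
#' @param bands A [transducer_bands()] object.
#' @param step Grid step within FM bands (kHz, default 2).
#' @return Numeric vector of frequencies (kHz), strictly increasing.
#' @export
freq_grid <- function(bands = transducer_bands(), step = 2) {
  f <- unlist(lapply(seq_len(nrow(bands$table)), function(i) {
    b <- bands$table[i, ]
    if (b$kind == "CW" || b$f_min == b$f_max) b$f_min
    else seq(b$f_min, b$f_max, by = step)
  }))
  sort(unique(f))
}

#' @rdname freq_grid
#' @param frequencies Frequency vector (kHz).
#' @return `grid_mask`: logical vector, `TRUE` where the frequency is usable
#'   (not inside an exclusion interval).
#' @export
grid_mask <- function(frequencies, bands = transducer_bands()) {
  mask <- rep(TRUE, length(frequencies))
  for (ex in bands$exclusions)
    mask[frequencies >= ex[1] & frequencies <= ex[2]] <- FALSE
  mask
}

band_of <- function(frequencies, bands) {
  out <- rep(NA_character_, length(frequencies))
  for (i in seq_len(nrow(bands$table))) {
    b <- bands$table[i, ]
    out[frequencies >= b$f_min & frequencies <= b$f_max] <- b$name
  }
  out
}
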