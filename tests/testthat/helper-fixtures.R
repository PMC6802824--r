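# Shared fixtures, built once per test run and cached. Communities for the
# clustering fixtures are gas + elastic mixtures whose resonance positions
# differ strongly between layers, so the standardized spectral shapes are
# well separated; the full deep-layer preset (all five modeled taxa) is
# forward-predicted once for the attribution tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_grid_freqs <- function() freq_grid(transducer_bands())

# three light layer communities with distinct spectral shapes
light_layers <- function(noise_sd = 2) {
  mk <- function(name, rng, taxa) layer_spec(name, rng, taxa, noise_sd)
  list(
    mk("upper", c(10, 22), data.frame(
      taxon = c("siphonophore_pneumatophore", "limacina"),
      model_class = c("gas_bearing", "elastic_shell"),
      mean_length = c(0.27, 0.75), sd_length = c(0.11, 0.12),
      density = c(50, 500), stringsAsFactors = FALSE)),
    mk("middle", c(22, 34), data.frame(
      taxon = c("siphonophore_pneumatophore", "limacina"),
      model_class = c("gas_bearing", "elastic_shell"),
      mean_length = c(1.23, 0.71), sd_length = c(0.31, 0.15),
      density = c(5, 100), stringsAsFactors = FALSE)),
    mk("lower", c(34, 46), data.frame(
      taxon = c("limacina"),
      model_class = c("elastic_shell"),
      mean_length = c(0.75), sd_length = c(0.12),
      density = c(1000), stringsAsFactors = FALSE)))
}

two_layer_sim <- function() fixture("two_layer_sim", function() {
  make_layered_echogram(light_layers()[1:2], test_grid_freqs(),
                        n_ping_blocks = 24, seed = 401, n_per_taxon = 50)
})

three_layer_sim <- function() fixture("three_layer_sim", function() {
  make_layered_echogram(light_layers(), test_grid_freqs(),
                        n_ping_blocks = 24, seed = 402, n_per_taxon = 50)
})

# deep-layer community preset, forward-predicted at the layer midpoint
deep_prediction <- function() fixture("deep_prediction", function() {
  comm <- make_community(deep_layer_spec(), n_per_taxon = 60, seed = 11)
  list(community = comm,
       prediction = predict_layer(comm, medium(depth = 83),
                                  test_grid_freqs()))
})
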