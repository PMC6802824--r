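medium:
  sound_speed: 1500.0
  density: 1026.0
  temperature: 283.15
bin_width: 0.1
layer_depth:
  surface: 17.0
  deep: 83.0
bands:
- name: ES18
  f_min: 18.0
  f_max: 18.0
  kind: CW
- name: ES38
  f_min: 38.0
  f_max: 38.0
  kind: CW
- name: ES70
  f_min: 47.0
  f_max: 90.0
  kind: FM
- name: ES120
  f_min: 95.0
  f_max: 160.0
  kind: FM
- name: ES200
  f_min: 180.0
  f_max: 240.0
  kind: FM
- name: ES333
  f_min: 280.0
  f_max: 420.0
  kind: FM
exclusions:
- - 240.0
  - 260.0
cluster_exclude_bands: ES333
models:
  euphausiids:
    class: fluid_like_cylinder
    g: 1.016
    h: 1.019
    length_to_width_ratio: 5.0
    orientation_mean: 20.0
    orientation_sd: 20.0
  decapod_shrimp:
    class: fluid_like_cylinder
    g: 1.016
    h: 1.019
    length_to_width_ratio: 5.0
    orientation_mean: 20.0
    orientation_sd: 20.0
  copepods:
    class: fluid_like_spheroid
    g: 0.949
    h: 0.995
    length_to_width_ratio: 2.55
    orientation_mean: 90.0
    orientation_sd: 30.0
  fish_without_swimbladder:
    class: fluid_like_cylinder
    g: 1.01
    h: 1.025
    length_to_width_ratio: 4.0
    orientation_mean: 0.0
    orientation_sd: 30.0
  argentina_sphyranea:
    class: fluid_like_cylinder
    g: 1.01
    h: 1.025
    length_to_width_ratio: 4.0
    orientation_mean: 0.0
    orientation_sd: 30.0
  pteropods:
    class: elastic_shell
    R: 0.5
    radius_fraction: 0.5
  limacina:
    class: elastic_shell
    R: 0.5
    radius_fraction: 0.5
  siphonophore_pneumatophore:
    class: gas_bearing
    length_is: gas_inclusion
    length_to_width_ratio: 2.35
    viscosity: 0.1
    surface_tension: 15.0
  swimbladdered_fish:
    class: gas_bearing
    length_is: gas_inclusion
    length_to_width_ratio: 1.63
    viscosity: 1.0
    surface_tension: 200.0
  crystallogobius_linearis:
    class: gas_bearing
    length_is: gas_inclusion
    length_to_width_ratio: 1.63
    viscosity: 1.0
    surface_tension: 200.0
  carapus_acus:
    class: gas_bearing
    length_is: gas_inclusion
    length_to_width_ratio: 2.75
    viscosity: 1.0
    surface_tension: 200.0
  other_swimbladdered_fish:
    class: gas_bearing
    length_is: body
    length_to_width_ratio: 1.5
    viscosity: 1.0
    surface_tension: 200.0
  jellyfish:
    class: excluded
  comb_jelly:
    class: excluded
  swimming_crabs:
    class: excluded
fish_no_swimbladder_as_gas: no
priors:
  siphonophore:
    length_to_width_ratio:
      kind: normal
      mu: 2.35
      sd: 0.3
    viscosity:
      kind: lognormal
      mu: -2.3
      sd: 1.0
    surface_tension:
      kind: lognormal
      mu: 2.7
      sd: 1.0
  swimbladdered_fish:
    length_to_width_ratio:
      kind: normal
      mu: .na
      sd: 0.2
    viscosity:
      kind: lognormal
      mu: 0.0
      sd: 1.0
    surface_tension:
      kind: lognormal
      mu: 5.3
      sd: 1.0
  copepods:
    length_to_radius:
      kind: normal
      mu: 5.5
      sd: 1.0
    g:
      kind: normal
      mu: 0.96
      sd: 0.0075
    h:
      kind: normal
      mu: 0.99
      sd: 0.0075
  euphausiids:
    length_to_radius:
      kind: normal
      mu: 10.0
      sd: 1.5
    g:
      kind: normal
      mu: 1.016
      sd: 0.0075
    h:
      kind: normal
      mu: 1.019
      sd: 0.0075
  fish_without_swimbladder:
    length_to_radius:
      kind: normal
      mu: 8.0
      sd: 1.5
    g:
      kind: normal
      mu: 1.01
      sd: 0.0075
    h:
      kind: normal
      mu: 1.025
      sd: 0.0075
  pteropods:
    R:
      kind: lognormal
      mu: -0.69
      sd: 0.4
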