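# Small synthetic study scenario: two gradient layers with random-field
# noise, a categorical cover layer, derived slope and distance layers, and
# two species with staggered temperature optima.
n_rows: 40
n_cols: 40
cellsize: 90
seed: 1
layers:
  - name: temperature
    base: 22
    gradient_x: -6
    gradient_y: 0
    corr_length: 8
    sd: 0.8
  - name: precipitation
    base: 1800
    gradient_x: 0
    gradient_y: -600
    corr_length: 10
    sd: 120
  - name: elevation
    base: 600
    gradient_x: 100
    gradient_y: 700
    corr_length: 8
    sd: 120
categorical:
  name: landcover
  n_classes: 5
  corr_length: 6
slope_from: elevation
distance_layers:
  - name: dist_water
    n_sources: 15
species:
  warm_species:
    "n": 25
    intercept: -1.2
    coefficients:
      temperature: [5.6, -4.0]
  cool_species:
    "n": 14
    intercept: -1.2
    coefficients:
      temperature: [-5.6, -4.0]
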