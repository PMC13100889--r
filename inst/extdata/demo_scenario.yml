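name: demo
n_level4: 5
branching:
- 4
- 3
- 2
level4_median_km2: 50364.0
area_sdlog: 0.4
predictor_vars:
- name: bio1
  kind: mean
  unit: degC
  mu: 10.0
  sigma: 4.0
  log: no
- name: bio7
  kind: mean
  unit: degC
  mu: 25.0
  sigma: 5.0
  log: no
- name: flow_min
  kind: mean
  unit: m3/s
  mu: 1.5
  sigma: 0.8
  log: yes
- name: roughness
  kind: mean
  unit: m
  mu: 3.2
  sigma: 0.7
  log: yes
- name: cropland
  kind: fraction
  unit: fraction
  mu: -1.0
  sigma: 1.5
- name: builtup
  kind: fraction
  unit: fraction
  mu: -3.0
  sigma: 1.2
- name: dam_density
  kind: density
  unit: dams/km2
  mu: -0.5
  sigma: 1.0
  rate: 0.004
range_decay: 4.0
effort:
  range_decay: 6.0
  sdlog: 0.8
detect_slope: 1.5
window:
- 1992
- 2015
species:
- species_id: sp01
  optima:
    bio1: 6.0
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp02
  optima:
    bio1: 7.1428571
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp03
  optima:
    bio1: 8.2857143
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp04
  optima:
    bio1: 9.4285714
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp05
  optima:
    bio1: 10.5714286
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp06
  optima:
    bio1: 11.7142857
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp07
  optima:
    bio1: 12.8571429
  breadths:
    bio1: 5.0
  max_prob: 0.95
- species_id: sp08
  optima:
    bio1: 14.0
  breadths:
    bio1: 5.0
  max_prob: 0.95
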