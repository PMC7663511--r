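# Demo pipeline configuration: synthetic data parameterized by the
# reference isotherm/kinetic fits for doxorubicin on oxidized nanotubes,
# plus a small planted trajectory fixture.
seed: 42
temperature_k: 298.15
isotherm:
  model: freundlich
  params:
    kF: 64.99
    inv_n: 0.1725
  ce_min: 0.067
  ce_max: 0.533
  n_points: 20
  noise_sd: 0.01
  mode: linearized
kinetics:
  model: pseudo_second
  params:
    qe: 4029.0
    k2: 6.92e-5
  noise_sd: 0.01
  qe_exp: 3900.0
  qe_rel_threshold: 0.2
trajectory:
  tube_n: 82
  tube_length_nm: 5
  box: [20, 80, 20]
  n_inside: 3
  surface_clusters: [6, 6]
  free_clusters: [4, 4, 4]
  min_separation: 2.0
  cluster_cutoff: 1.0
  contact_cutoff: 0.5
  mode: cluster
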