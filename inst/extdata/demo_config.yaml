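# Demo pipeline configuration: a two-population dynamic ensemble measured
# under three excitation conditions, per-residue secondary-structure
# quantification and a two-component 31P decomposition.
seed: 1
output_dir: results
physics:
  r_eff_angstrom: 1.117
  kappa: 0.5773502691896258     # 1/sqrt(3), theoretical Lee-Goldburg value
  d_rigid_hz: null              # set to override the computed rigid limit
mas:
  nu_r: 5000
  n_points: 9
powder:
  n_beta: 128
  n_gamma: 64
fit:
  uncertainty: jackknife
ensemble:
  label: helix-ensemble
  noise_sd: 0.0
  populations:
    - {S: 0.85, weight: 0.5, label: rigid-helix}
    - {S: 0.34, weight: 0.5, label: mobile-terminus}
  conditions:
    - {excitation: cp, t_cp_us: 20}
    - {excitation: cp, t_cp_us: 700}
    - {excitation: direct}
regions:
  noise_sd: 0.0
  sheet_fractions: {Met: 0.23, Arg: 0.22, His: 0.05}
p31:
  delta_iso: -1
  delta_sigma: 45
  lb: 50
  iso_fraction: 0.19
  iso_width: 100
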