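# Demo configuration: synthetic free + complex ensembles and the full
# ensemble-to-landscape analysis.
seed: 42
temperature: 300
contact_cutoff: 4.5
log_level: info

chains:
  idp: A
  partner: B

regions:
  alpha_A: [120, 129]
  alpha_B: [134, 144]

hrc:
  residues: [128, 134, 137, 138]
  threshold: 15
  mode: pairs

synth:
  free:
    n_frames: 300
    p_hrc: 0.4
    helix_profile:
      - {from: 120, to: 129, p: 0.5}
      - {from: 134, to: 144, p: 0.15}
  complex:
    n_frames: 400
    states:
      - {name: F, fraction: 0.4, d_mean: 40, d_sd: 2.0, q_mean: 0.00, q_sd: 0.00}
      - {name: E, fraction: 0.2, d_mean: 26, d_sd: 1.5, q_mean: 0.00, q_sd: 0.00}
      - {name: B, fraction: 0.4, d_mean: 19, d_sd: 0.5, q_mean: 0.85, q_sd: 0.05}

fel:
  axis1: {name: d_com, min: 10, max: 50, width: 1.0}
  axis2: {name: n_native, min: -0.5, max: 13.5, width: 1.0}
  energy_cap: 20
  merge_barrier: 3
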