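# Default pipeline configuration: a calibrated cell-level simulation at a
# reduced scale, with estimation settings matching the reference protocol
# (10,000 kept draws, burn-in 5,000 for the iterative engine, 95% CrI).
mode: simulate
seed: 1
S: 10000
engine: conjugate
burn_in: 5000
chains: 2
output_dir: pomediate_out
simulate:
  level: cell
  n_per_race: [1400000, 300000]
  prevalence:
    non_black: [15.1, 14.0, 29.2, 41.7]   # (m1,m2) = (1,1), (2,1), (1,2), (2,2)
    black: [9.7, 14.7, 24.2, 51.3]
  outcomes:
    cesarean:
      baseline: 0.25
      te_target: 0.0402
      cde_targets: {M1M2: 0.0201402}
    gest_htn:
      baseline: 0.05
      te_target: 0.0105
      cde_targets: {M1M2: 0.012516}
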