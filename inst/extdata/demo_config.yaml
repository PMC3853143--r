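# Four-gene transcriptional repression cascade (TetR -| LacI -| CI -| Eyfp)
# with calibrated per-gene level ranges: level-matched production/degradation
# pairs place each gene's fixed point on its target steady state.
genes:
  - name: TetR
    repressor: ~
    hill_K: 1000
    hill_n: 2
  - name: LacI
    repressor: TetR
    hill_K: 1000
    hill_n: 2
  - name: CI
    repressor: LacI
    hill_K: 1000
    hill_n: 2
  - name: Eyfp
    repressor: CI
    hill_K: 1000
    hill_n: 2

params:
  # basal production rates, nM per time step (not part of the scanned grid);
  # CI's basal rate dominates its production because LacI silences its promoter
  p0:
    TetR: 0
    LacI: 0
    CI: 6.5
    Eyfp: 0

levels:
  n_levels: 5
  production:          # nM per time step
    default: [0, 6000]
    TetR: [0, 200]
    LacI: [0, 12000]
    CI: [0, 200]
    Eyfp: [0, 6540]
  degradation:         # per time step
    default: [0, 0.2]
    CI: [0.018, 0.0255]

target:
  z:                   # steady-state concentrations, nM
    TetR: 1000
    LacI: 30000
    CI: 300
    Eyfp: 30000
  tolerance: 0.20
  sentinel: 15

noise:
  rel: 0.1             # parameter perturbation sd as fraction of nominal
  extrinsic_sigma: 10  # additive extrinsic noise sd, nM per step

simulation:
  T: 100
  substeps: 1
  abort_ceiling: 1.0e6

clustering:
  linkage: average
  cut_height: 2.5
  threshold: 0.9
  min_size: 10

seed: 1
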