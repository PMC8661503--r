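# Demonstration study: cumulative-EdU kinetics, pulse-chase exit index and
# reporter flow timecourse for an MGE-like differentiation under vehicle
# (DMSO) vs TGF-beta receptor inhibition (LY). Kinetic ground truths are the
# published day-22 estimates; sizes are kept small so the demo runs in
# seconds.
seed: 20211207
labeling:
  times: [2, 4, 8, 16, 24]
  n_cells_per_field: 200
  n_fields: 6
  n_replicates: 2
  fit_policy: plateau_exclude
  subpops:
    marker_pos: {gf: 0.90, proportion: 0.8}
    marker_neg: {gf: 0.75, proportion: 0.2}
  conditions:
    DMSO:
      marker_pos: {tc: 39.98, ts: 16.51}
      marker_neg: {tc: 38.80, ts: 16.60}
    LY:
      marker_pos: {tc: 45.65, ts: 21.76}
      marker_neg: {tc: 40.26, ts: 16.11}
pulse_chase:
  pulse: 2
  chase: 48
  quit_prob:
    DMSO: 0.30
    LY: 0.15
flow:
  days: [25, 35, 45]
  n_events: 5000
  n_replicates: 3
  percentile: 99.9
  conditions:
    control: {condition_scale: 1.0}
    LY: {condition_scale: 0.3}
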