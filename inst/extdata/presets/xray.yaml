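# Half-field X-ray series (no cisplatin): four-group experiment with
# per-group speed laws calibrated to the published cohort median (um/h)
# and quartiles. Alias id: fig2.
name: xray
seed: 1
n_cells_per_group: 100
n_replicates: 3
n_frames: 97
frame_interval: 15
step_law: fixed
cell_radius: 10
dish:
  diameter: 60
  boundary_x: 0
  exclusion_half_width: 10
  penumbra_sigma: 1
  nominal_dose: 2
groups:
  Control:
    speed_median: 5.73
    speed_q1: 3.31
    speed_q3: 9.49
    persistence: 0
  Uniform:
    speed_median: 4.99
    speed_q1: 2.90
    speed_q3: 8.36
    persistence: 0
  In-field:
    speed_median: 5.86
    speed_q1: 3.35
    speed_q3: 9.78
    persistence: 0
  Out-of-field:
    speed_median: 4.66
    speed_q1: 2.68
    speed_q3: 7.84
    persistence: 0
fucci:
  untreated:
    red: 0.55
    yellow: 0.12
    green: 0.33
fucci_n: 300
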