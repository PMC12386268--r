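# Cisplatin + half-field X-ray series: cisplatin 5 uM for 1 h plus 14 h
# incubation before exposure (G2 arrest: 70.3% of cells green). Speed laws
# calibrated to the published cohort median (um/h) and quartiles.
# Alias id: fig4.
name: cisplatin
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
    speed_median: 4.83
    speed_q1: 2.66
    speed_q3: 8.11
    persistence: 0
  Uniform:
    speed_median: 5.28
    speed_q1: 3.05
    speed_q3: 8.86
    persistence: 0
  In-field:
    speed_median: 5.03
    speed_q1: 2.92
    speed_q3: 8.21
    persistence: 0
  Out-of-field:
    speed_median: 5.17
    speed_q1: 3.04
    speed_q3: 8.32
    persistence: 0
fucci:
  untreated:
    red: 0.55
    yellow: 0.12
    green: 0.33
  cisplatin:
    red: 0.197
    yellow: 0.100
    green: 0.703
fucci_n: 300
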