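# Demonstration pipeline configuration: a quarter-scale simulated scene
# with a zoospore proximal-vs-distant potassium comparison.
seed: 42
pixel_size: 1.3
frame_interval: 0.0735
threshold: 110
noise_sd: 8
scene:
  field_width: 510
  field_height: 340
  n_frames: 40
grid:
  cell_side: 170
rules:
  - species: bacterium
    radius_max: 4.5
    max_linking_distance: 2
  - species: zoospore
    radius_min: 4.5
    radius_max: 10
    max_linking_distance: 15
  - species: vorticella
    radius_min: 10
    max_linking_distance: 60
microenvironments:
  - name: proximal_kcl
    species: zoospore
    cells: [A1, A2, A3]
    frames: [1, 40]
  - name: distant_kcl
    species: zoospore
    cells: [B1, B2, B3]
    frames: [1, 40]
comparisons:
  - [proximal_kcl, distant_kcl]
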