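# Demonstration preset: miniature absorption energy scan of the 7 cm
# adipose + 1 cm glandular concentric phantom at coarse resolution.
task: energy_scan
phantom:
  type: concentric
  outer_diameter_cm: 7
  outer_material: adipose
  detail_diameter_cm: 1
  detail_material: glandular
  pixel_size_um: 480
geometry:
  n_projections: 120
  detector_pixel_um: 480
  n_rows: 3
energies: [20, 26, 32]
mgd_mGy: 20
modality: absorption
n_slices: 3
seed: 1
margin_px: 2
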