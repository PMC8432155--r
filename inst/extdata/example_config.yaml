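# Example study configuration for the polyQscreen pipeline.
# Frozen analysis constants are the package defaults; only the plate
# layout and generator geometry are set here.
nuclear_threshold: 144
acn_threshold: 2000
area_threshold: 969
na_tolerance: 150
ena_tolerance: 150
tot_tolerance: 1000
control_label: GFP
lines: [GFP, CAG71, CAG122]
severity:
  GFP: 0
  CAG71: 1
  CAG122: 2
days: [0, 7, 11, 14]
wells_per_line: 4
seed: 1
template:
  field_shape: [256, 256]
  n_nuclei: 20
  ena_density: 2
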