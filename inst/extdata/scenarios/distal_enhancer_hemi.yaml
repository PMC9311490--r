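schema_version: 1
scenario_name: distal_enhancer_hemi
genotype: hemizygous
construct_class: distal_enhancer
alleles:
- channel: MS2
  construct: full
  gene_length: 6.5
  loop_start: 0.1
  loop_length: 1.3
  telegraph:
    k_on_max: 0.15
    k_off: 0.015
    k_load: 20.16
    v_el: 1.8
    x_boundary: 0.5
    steepness: 30.0
  sequester_rate: 0.0
  sequester_dwell: 0.0
  parent_of_origin: paternal
n_embryos: 4
nuclei_grid:
- 24
- 26
frame_interval: 20.0
nc13_duration: 15.0
nc14_duration: 50.0
hub:
  capacity: 400.0
  replenish_rate: 0.0
  background_demand_nc13: 0.6
  background_demand_nc14_start: 8.0
  background_demand_nc14_end: 12.6
  background_dwell: 17.0
noise_sd: 10.0
unit_intensity: 1.0
seed: 20220711
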