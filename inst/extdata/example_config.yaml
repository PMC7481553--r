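# Example lfaquant run configuration: full simulate -> quantify -> calibrate
# pipeline on a synthetic duplex sandwich experiment (0-20 nM, 5 levels x 3
# technical replicates, linear response).
output_dir: lfaquant_run

simulate:
  analyte_a: CRP
  analyte_b: IL6
  concentrations_a: [0, 2.5, 5, 10, 20]
  concentrations_b: [0, 2.5, 5, 10, 20]
  unit_a: nM
  unit_b: nM
  response_a: {type: linear, slope: 150}
  response_b: {type: linear, slope: 150}
  control_amplitude: 4000
  replicates: 3
  crosstalk: 0
  seed: 1
  strip:
    height_px: 120
    width_px: 30
    bit_depth: 16
    band_centers: [40, 90]
    band_sigma_px: 3
    background_level: 500
    noise_sd: 60        # 2% of the max test-band amplitude (150 * 20)

quantify:
  n_lanes: 1
  expected_bands: 2
  band_rows: [40, 90]   # printed line positions on the membrane
  smoothing_window: 5
  boundary_fraction: 0.1
  margin_factor: 2

calibrate:
  stage: raw
  include_saturated: false
  definitions_id: blank_1.645sd
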