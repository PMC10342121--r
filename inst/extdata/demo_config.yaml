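# Demo configuration for the xanthomap pipeline: a small simulated
# macular map (1.5 x 1.5 mm at 50 um pixels) with an nu1 calibration
# built from a 6-level x 3-replicate mixture series.
generator:
  seed: 11
  laser_nm: 514
  noise_sd: 0.02
  n_levels: 6
  n_reps: 3
  geometry:
    map_extent: 1.5
    pixel_size: 50
preprocess:
  z_threshold: 8
calibration:
  estimator: nu1
mapping:
  estimator: nu1
  segmentation_mode: fixed
output:
  dir: xanthomap_demo_out
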