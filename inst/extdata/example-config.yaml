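# Example pipeline configuration.  Fields mirror generator_config() /
# pipeline_config() exactly; omitted fields keep their defaults.
generator:
  n_cameras: 5
  frames_per_camera: 100
  crowd_dist:
    family: nbinom
    size: 1.2
    mu: 8
  crowd_range: [2, 67]
  group_size_dist: [0.55, 0.30, 0.10, 0.05]
  within_group_spacing_m: [0.9, 2.6]
  clustering_strength: 0.6
  attraction_scale_m: 2.0
  threshold_m: 1.5
  seed: 42
viewshed:
  area_m2: 650
  aspect_ratio: 2.0
nullmodel:
  areas_m2: [650, 300, 150]
  aspect_ratio: 2.0
  n_values: [2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30]
  replicates: 5000
  boundary: plain
analysis:
  ci_level_person: 0.9995
  ci_level_frame: 0.995
  n_bins: 20
  winsorize: true
log_level: info
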