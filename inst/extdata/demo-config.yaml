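# Demo pipeline configuration: a small synthetic fleet that runs end to end
# in a few minutes on one core. Field names mirror world_config(),
# fleet_config() and pipeline_config().
world:
  lon_min: 0
  lon_max: 15
  lat_min: -10
  lat_max: 10
  seed: 7
fleet:
  n_vessels: 30
  seed: 11
days: 60
min_gap_h: 12
min_shore_nmi: 50
min_reception: 10
cap_h: 336
max_speed_knots: 10
seed: 1
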