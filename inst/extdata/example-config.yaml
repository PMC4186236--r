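# Example run configuration: only the keys that differ from the defaults
# need to be given; everything else is filled from dac_default_config().
world:
  noise_sd: 0.2
  sensor_range: 25
al:
  eta: 0.2
cl:
  mode: egocentric
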