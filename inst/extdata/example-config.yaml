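# Example run configuration: the main myelinated-axon experiment.
# Unset keys take their defaults (see ?run_config).
preset: Myelin1
protocol: dadf
window_ms: 40
site_stride: 1
periaxonal_ends: sealed
seed: 1
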