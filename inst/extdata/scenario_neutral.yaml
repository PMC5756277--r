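schema_version: 1
name: neutral
notes: valence-symmetric medium-strength connections (canonical defaults)
weight_overrides: []
stimulus_levels: []
initial_values: []
state_params: []
hebbian_overrides: []
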