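schema_version: 1
name: atheist
notes: 'avoidant attachment: Self-ownership 1.0, God-ownership 0.3, weak religious-source
  couplings, goal state 0.8'
weight_overrides:
  w11a.1: 1.0
  w12a.1: 1.0
  w17a.1: 1.0
  w17b.1: 1.0
  w17c.1: 1.0
  w19a.1: 1.0
  w19b.1: 1.0
  w21b.1: 1.0
  w22a.1: 1.0
  w11a.2: 1.0
  w12a.2: 1.0
  w17a.2: 1.0
  w17b.2: 1.0
  w17c.2: 1.0
  w19a.2: 1.0
  w19b.2: 1.0
  w21b.2: 1.0
  w22a.2: 1.0
  w11b.1: 0.29999999999999999
  w12b.1: 0.29999999999999999
  w18a.1: 0.29999999999999999
  w18b.1: 0.29999999999999999
  w20a.1: 0.29999999999999999
  w20b.1: 0.29999999999999999
  w21a.1: 0.29999999999999999
  w22b.1: 0.29999999999999999
  w11b.2: 0.29999999999999999
  w12b.2: 0.29999999999999999
  w18a.2: 0.29999999999999999
  w18b.2: 0.29999999999999999
  w20a.2: 0.29999999999999999
  w20b.2: 0.29999999999999999
  w21a.2: 0.29999999999999999
  w22b.2: 0.29999999999999999
  w1.1: 0.29999999999999999
  w2.1: 0.29999999999999999
  w3.1: 0.29999999999999999
  w4.1: 0.29999999999999999
  w1.2: 0.29999999999999999
  w2.2: 0.29999999999999999
  w3.2: 0.29999999999999999
  w4.2: 0.29999999999999999
stimulus_levels: []
initial_values:
  gs: 0.80000000000000004
state_params: []
hebbian_overrides: []
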