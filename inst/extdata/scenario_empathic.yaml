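schema_version: 1
name: empathic
notes: 'empathic God-image: empathic connections 0.8, dis-empathic 0.1'
weight_overrides:
  w1.1: 0.80000000000000004
  w2.1: 0.80000000000000004
  w3.1: 0.80000000000000004
  w4.1: 0.80000000000000004
  w5.1: 0.80000000000000004
  w6.1: 0.80000000000000004
  w7a.1: 0.80000000000000004
  w7b.1: 0.80000000000000004
  w7c.1: 0.80000000000000004
  w7d.1: 0.80000000000000004
  w8a.1: 0.80000000000000004
  w8b.1: 0.80000000000000004
  w8c.1: 0.80000000000000004
  w9a.1: 0.80000000000000004
  w9b.1: 0.80000000000000004
  w9c.1: 0.80000000000000004
  w9d.1: 0.80000000000000004
  w10.1: 0.80000000000000004
  w11a.1: 0.80000000000000004
  w11b.1: 0.80000000000000004
  w11c.1: 0.80000000000000004
  w11d.1: 0.80000000000000004
  w11e.1: 0.80000000000000004
  w12a.1: 0.80000000000000004
  w12b.1: 0.80000000000000004
  w12c.1: 0.80000000000000004
  w12d.1: 0.80000000000000004
  w12e.1: 0.80000000000000004
  w12f.1: 0.80000000000000004
  w13a.1: 0.80000000000000004
  w13b.1: 0.80000000000000004
  w13c.1: 0.80000000000000004
  w13d.1: 0.80000000000000004
  w15a.1: 0.80000000000000004
  w15b.1: 0.80000000000000004
  w15c.1: 0.80000000000000004
  w16a.1: 0.80000000000000004
  w16b.1: 0.80000000000000004
  w17a.1: 0.80000000000000004
  w17b.1: 0.80000000000000004
  w17c.1: 0.80000000000000004
  w18a.1: 0.80000000000000004
  w18b.1: 0.80000000000000004
  w19a.1: 0.80000000000000004
  w19b.1: 0.80000000000000004
  w20a.1: 0.80000000000000004
  w20b.1: 0.80000000000000004
  w21a.1: 0.80000000000000004
  w21b.1: 0.80000000000000004
  w21c.1: 0.80000000000000004
  w22a.1: 0.80000000000000004
  w22b.1: 0.80000000000000004
  w22c.1: 0.80000000000000004
  w23.1: 0.80000000000000004
  w24.1: 0.80000000000000004
  w25.1: 0.80000000000000004
  w1.2: 0.10000000000000001
  w2.2: 0.10000000000000001
  w3.2: 0.10000000000000001
  w4.2: 0.10000000000000001
  w5.2: 0.10000000000000001
  w6.2: 0.10000000000000001
  w7a.2: 0.10000000000000001
  w7b.2: 0.10000000000000001
  w7c.2: 0.10000000000000001
  w7d.2: 0.10000000000000001
  w8a.2: 0.10000000000000001
  w8b.2: 0.10000000000000001
  w8c.2: 0.10000000000000001
  w9a.2: 0.10000000000000001
  w9b.2: 0.10000000000000001
  w9c.2: 0.10000000000000001
  w9d.2: 0.10000000000000001
  w10.2: 0.10000000000000001
  w11a.2: 0.10000000000000001
  w11b.2: 0.10000000000000001
  w11c.2: 0.10000000000000001
  w11d.2: 0.10000000000000001
  w11e.2: 0.10000000000000001
  w12a.2: 0.10000000000000001
  w12b.2: 0.10000000000000001
  w12c.2: 0.10000000000000001
  w12d.2: 0.10000000000000001
  w12e.2: 0.10000000000000001
  w12f.2: 0.10000000000000001
  w13a.2: 0.10000000000000001
  w13b.2: 0.10000000000000001
  w13c.2: 0.10000000000000001
  w13d.2: 0.10000000000000001
  w15a.2: 0.10000000000000001
  w15b.2: 0.10000000000000001
  w15c.2: 0.10000000000000001
  w16a.2: 0.10000000000000001
  w16b.2: 0.10000000000000001
  w17a.2: 0.10000000000000001
  w17b.2: 0.10000000000000001
  w17c.2: 0.10000000000000001
  w18a.2: 0.10000000000000001
  w18b.2: 0.10000000000000001
  w19a.2: 0.10000000000000001
  w19b.2: 0.10000000000000001
  w20a.2: 0.10000000000000001
  w20b.2: 0.10000000000000001
  w21a.2: 0.10000000000000001
  w21b.2: 0.10000000000000001
  w21c.2: 0.10000000000000001
  w22a.2: 0.10000000000000001
  w22b.2: 0.10000000000000001
  w22c.2: 0.10000000000000001
  w23.2: 0.10000000000000001
  w24.2: 0.10000000000000001
  w25.2: 0.10000000000000001
stimulus_levels: []
initial_values: []
state_params: []
hebbian_overrides: []
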