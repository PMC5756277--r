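schema_version: 1
name: asd
notes: 'ASD with social-domain impairment: weak mirroring/mentalizing (0.3), dis-empathic
  God-image and stimuli dominant'
weight_overrides:
  w1.1: 0.80000000000000004
  w2.1: 0.80000000000000004
  w3.1: 0.80000000000000004
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
  w1.2: 1.0
  w2.2: 1.0
  w3.2: 1.0
  w7a.2: 1.0
  w7b.2: 1.0
  w7c.2: 1.0
  w7d.2: 1.0
  w8a.2: 1.0
  w8b.2: 1.0
  w8c.2: 1.0
  w9a.2: 1.0
  w9b.2: 1.0
  w9c.2: 1.0
  w9d.2: 1.0
  w10.1: 0.29999999999999999
  w11c.1: 0.29999999999999999
  w12c.1: 0.29999999999999999
  w13a.1: 0.29999999999999999
  w13b.1: 0.29999999999999999
  w13c.1: 0.29999999999999999
  w16a.1: 0.29999999999999999
  w10.2: 0.29999999999999999
  w11c.2: 0.29999999999999999
  w12c.2: 0.29999999999999999
  w13a.2: 0.29999999999999999
  w13b.2: 0.29999999999999999
  w13c.2: 0.29999999999999999
  w16a.2: 0.29999999999999999
stimulus_levels:
  ws_god_action_1: 0.5
  ws_god_image_1: 0.5
  ws_god_emotion_1: 0.5
  ws_god_action_2: 1.0
  ws_god_image_2: 1.0
  ws_god_emotion_2: 1.0
initial_values: []
state_params: []
hebbian_overrides: []
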