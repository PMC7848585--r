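preset: eight_object_two_scene
scene_ids:
- X
- 'Y'
object_ids:
- A1
- A2
- A3
- A4
- B1
- B2
- B3
- B4
contingency:
  scene:
  - X
  - X
  - X
  - X
  - X
  - X
  - X
  - X
  - 'Y'
  - 'Y'
  - 'Y'
  - 'Y'
  - 'Y'
  - 'Y'
  - 'Y'
  - 'Y'
  object:
  - A1
  - A2
  - A3
  - A4
  - B1
  - B2
  - B3
  - B4
  - A1
  - A2
  - A3
  - A4
  - B1
  - B2
  - B3
  - B4
  reward_volume:
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.3
  - 0.3
  - 0.3
  - 0.3
reward_large: 0.3
reward_small: 0.1
reward_signal_large: 1.0
reward_signal_small: -0.5
sequencing: block
block_length: 20
n_trials: 160
offer_rule: good_vs_bad
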