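{
  "type": "disc",
  "radius": 8.97,
  "separation": 13.455,
  "sd": 3.89,
  "reward_value": 100,
  "penalty_value": -100,
  "distortion": {"gamma": 0.88, "p0": 0.76}
}
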