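{
  "type": "rect",
  "sd": 3.05,
  "bar_width": 4.575,
  "gap": 3.43125,
  "distortion": {"gamma": 0.88, "p0": 0.76},
  "super_additivity_b": 0.063
}
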