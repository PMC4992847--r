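{
  "model": {
    "name": "pwl2d"
  },
  "protocol": [
    {"kind": "clamp", "v_c": 15.0, "tau_c": 5.0}
  ],
  "numerics": {
    "dt": 0.01,
    "horizon": 60.0
  }
}
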