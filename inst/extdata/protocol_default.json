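{
  "version": 1,
  "name": "default",
  "segments": [
    {"kind": "baseline", "duration_s": 60, "fco2_percent": 0},
    {"kind": "box", "duration_s": 45, "fco2_percent": 1},
    {"kind": "baseline", "duration_s": 45, "fco2_percent": 0},
    {"kind": "box", "duration_s": 45, "fco2_percent": 3},
    {"kind": "baseline", "duration_s": 45, "fco2_percent": 0},
    {"kind": "box", "duration_s": 45, "fco2_percent": 5},
    {"kind": "baseline", "duration_s": 45, "fco2_percent": 0},
    {"kind": "ramp", "duration_s": 60, "fco2_percent": 5, "start_fco2_percent": 0},
    {"kind": "baseline", "duration_s": 45, "fco2_percent": 0},
    {"kind": "half_sine", "duration_s": 60, "fco2_percent": 5},
    {"kind": "baseline", "duration_s": 60, "fco2_percent": 0}
  ]
}
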