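{
  "scenario": {
    "type": "subject",
    "subject": {"tidal_volume": 500, "rate_baseline": 14, "vo2": 0.25,
                "vco2": 0.2, "dead_space": 150, "frc": 3000,
                "chemoreflex_gain": 0.3}
  },
  "circuit": {"inlet_position": "near_sampling_port", "port_volume": 50,
              "sampling_delay": 3, "sample_rate": 60,
              "analyzer_noise_sd": 0.05},
  "controller": {"system": "reservoir",
                 "reservoir": {"total_flow_lpm": 8, "fo2": 0.21,
                               "volume_ml": 700}}
}
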