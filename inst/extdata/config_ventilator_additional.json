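{
  "scenario": {
    "type": "ventilator",
    "settings": {"mode": "volume_control", "tidal_volume": 500,
                 "t_insp": 1.5, "rate": 12, "peep": 5},
    "mechanics": {"compliance": 50, "resistance": 5, "frc": 3000,
                  "dead_space": 150}
  },
  "circuit": {"inlet_position": "near_flow_sensor", "mixing_volume": 300,
              "transport_volume": 500, "sampling_delay": 3,
              "sample_rate": 60, "analyzer_noise_sd": 0.05},
  "controller": {"system": "additional", "additional_fco2_percent": 100,
                 "sensor_gain": 1.0, "setpoint_cap_lpm": 5}
}
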