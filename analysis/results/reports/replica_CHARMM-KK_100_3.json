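{
  "seed": 1,
  "config_hash": "568851f1",
  "package_version": "0.1.0",
  "replica": 3,
  "condition": "CHARMM-KK",
  "voltage_mV": 100,
  "duration_us": 1,
  "n_events": 0,
  "prevalent_state": "down/down",
  "down_fraction": [1, 1],
  "lipid_in_cavity": true,
  "lipid_cavity_fraction": 0.6
}
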