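{
  "seed": 1,
  "config_hash": "568851f1",
  "package_version": "0.1.0",
  "populations": [
    {
      "I": 93.075,
      "II": 6.925,
      "II'": 0,
      "III": 0,
      "IV": 0,
      "V": 0,
      "VI": 0,
      "VII": 0,
      "other": 0,
      "_row": "AMBER-KK"
    },
    {
      "I": 34.7333333333333,
      "II": 32.9833333333333,
      "II'": 0,
      "III": 32.2833333333333,
      "IV": 0,
      "V": 0,
      "VI": 0,
      "VII": 0,
      "other": 0,
      "_row": "CHARMM-KK"
    }
  ],
  "conductance": {
    "AMBER-KK@100": {
      "events": [2, 4, 2],
      "mean_pS": 4.272471024,
      "sd_pS": 1.85003422185846
    },
    "CHARMM-KK@100": {
      "events": [0, 0, 0],
      "mean_pS": 0,
      "sd_pS": 0
    }
  },
  "replicas": [
    {
      "condition": "AMBER-KK",
      "voltage_mV": 100,
      "replica": 1,
      "n_events": 2,
      "prevalent_state": "up/up",
      "lipid_in_cavity": false
    },
    {
      "condition": "AMBER-KK",
      "voltage_mV": 100,
      "replica": 2,
      "n_events": 4,
      "prevalent_state": "up/up",
      "lipid_in_cavity": false
    },
    {
      "condition": "AMBER-KK",
      "voltage_mV": 100,
      "replica": 3,
      "n_events": 2,
      "prevalent_state": "up/up",
      "lipid_in_cavity": false
    },
    {
      "condition": "CHARMM-KK",
      "voltage_mV": 100,
      "replica": 1,
      "n_events": 0,
      "prevalent_state": "down/down",
      "lipid_in_cavity": true
    },
    {
      "condition": "CHARMM-KK",
      "voltage_mV": 100,
      "replica": 2,
      "n_events": 0,
      "prevalent_state": "down/down",
      "lipid_in_cavity": true
    },
    {
      "condition": "CHARMM-KK",
      "voltage_mV": 100,
      "replica": 3,
      "n_events": 0,
      "prevalent_state": "down/down",
      "lipid_in_cavity": true
    }
  ]
}
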