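{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "poreflow pipeline report",
  "description": "Structural schema for per-replica and aggregate pipeline reports.",
  "type": "object",
  "required": {
    "seed": "integer",
    "config_hash": "string",
    "package_version": "string"
  },
  "properties": {
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "package_version": {"type": "string"},
    "replica": {"type": "integer"},
    "condition": {"type": "string"},
    "voltage_mV": {"type": "number"},
    "duration_us": {"type": "number"},
    "n_events": {"type": "integer"},
    "prevalent_state": {"type": "string"},
    "lipid_in_cavity": {"type": "boolean"},
    "populations": {"type": "object"},
    "conductance": {"type": "object"},
    "replicas": {"type": "array"}
  }
}
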