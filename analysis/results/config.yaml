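registry: registry.yaml
output_dir: reports
embedding:
  sigma: 150.0
  n_landmarks: 150.0
dbscan:
  eps: 20.0
seed: 1.0
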