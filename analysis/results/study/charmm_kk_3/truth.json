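{"n_events":0,"events":[],"state_occupancy":{"I":0.329,"II":0.3105,"III":0.3605},"down_fraction":1,"lipid_fraction":0.6}
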