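{"n_events":2,"events":[{"ion":1,"entry_frame":1191,"completion_frame":1196,"direction":1},{"ion":1,"entry_frame":2784,"completion_frame":2789,"direction":1}],"state_occupancy":{"I":0.942,"II":0.058},"down_fraction":0,"lipid_fraction":0}
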