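{"n_events":4,"events":[{"ion":1,"entry_frame":891,"completion_frame":896,"direction":1},{"ion":1,"entry_frame":1890,"completion_frame":1895,"direction":1},{"ion":1,"entry_frame":2085,"completion_frame":2090,"direction":1},{"ion":1,"entry_frame":3504,"completion_frame":3509,"direction":1}],"state_occupancy":{"I":0.925,"II":0.075},"down_fraction":0,"lipid_fraction":0}
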