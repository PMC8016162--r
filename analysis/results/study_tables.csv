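"force_field","init_config","voltage_mV","mean_pS","sd_pS","n"
"AMBER","KK",100,4.272471024,1.85003422185846,3
"AMBER","KK",200,5.874647658,3.2375598882523,3
"AMBER","KWK",100,1.602176634,1.602176634,3
"CHARMM","KK",200,2.937323829,5.08759411011076,3
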