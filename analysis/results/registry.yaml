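runs:
- force_field: AMBER
  init_config: KK
  voltage_mV: 100.0
  replica: 1
  duration_us: 1.0
  path: study/amber_kk_1
- force_field: AMBER
  init_config: KK
  voltage_mV: 100.0
  replica: 2
  duration_us: 1.0
  path: study/amber_kk_2
- force_field: AMBER
  init_config: KK
  voltage_mV: 100.0
  replica: 3
  duration_us: 1.0
  path: study/amber_kk_3
- force_field: CHARMM
  init_config: KK
  voltage_mV: 100.0
  replica: 1
  duration_us: 1.0
  path: study/charmm_kk_1
- force_field: CHARMM
  init_config: KK
  voltage_mV: 100.0
  replica: 2
  duration_us: 1.0
  path: study/charmm_kk_2
- force_field: CHARMM
  init_config: KK
  voltage_mV: 100.0
  replica: 3
  duration_us: 1.0
  path: study/charmm_kk_3
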