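# Summary of the 32 production runs of the force-field comparison study
# (AMBER ff14SB vs CHARMM36m, TRAAK channel): per-run membrane potential,
# prevalent gating state, lipid cavity flag and observed conduction-event
# count. Each run lasted 1 microsecond.
runs:
  - {force_field: AMBER, init_config: KK, voltage_mV: 0, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KK, voltage_mV: 0, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KK, voltage_mV: 100, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 2}
  - {force_field: AMBER, init_config: KK, voltage_mV: 100, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 4}
  - {force_field: AMBER, init_config: KK, voltage_mV: 100, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 2}
  - {force_field: AMBER, init_config: KK, voltage_mV: 200, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 3}
  - {force_field: AMBER, init_config: KK, voltage_mV: 200, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 11}
  - {force_field: AMBER, init_config: KK, voltage_mV: 200, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 8}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 0, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 0, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 100, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 1, after_water_exit: yes}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 100, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 100, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 2, after_water_exit: yes}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 200, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 200, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: AMBER, init_config: KWK, voltage_mV: 200, replica: 3, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 0, replica: 1, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 0, replica: 2, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 100, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 100, replica: 2, duration_us: 1, prevalent_state: down/up, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 100, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 200, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 200, replica: 2, duration_us: 1, prevalent_state: down/up, lipids_in_cavity: yes, events: 11}
  - {force_field: CHARMM, init_config: KK, voltage_mV: 200, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 0, replica: 1, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 0, replica: 2, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 100, replica: 1, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 100, replica: 2, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 100, replica: 3, duration_us: 1, prevalent_state: up/up, lipids_in_cavity: no, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 200, replica: 1, duration_us: 1, prevalent_state: down/up, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 200, replica: 2, duration_us: 1, prevalent_state: down/up, lipids_in_cavity: yes, events: 0}
  - {force_field: CHARMM, init_config: KWK, voltage_mV: 200, replica: 3, duration_us: 1, prevalent_state: up/down, lipids_in_cavity: yes, events: 0}
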