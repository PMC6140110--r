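# Point-source extracellular stimulation of the default myelinated axon
rho_ex_ohm_m: 3.0
I_ex_mA: -1.0
pulse_ms: 0.1
electrode_node: 20
electrode_distance_mm: 1.0
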