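# Default myelinated axon geometry and intracellular velocity protocol
kind: myelinated
D_um: 2.0
Ln_um: 2.0
Li_um: 200.0
n_nodes: 141
Rax_ohm_cm: 100.0
stimulus:
  site: 20
  amplitude_nA: 0.1
  duration_ms: 1.0
velocity_nodes: [40, 90]
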