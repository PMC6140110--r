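# Default unmyelinated (cable) axon geometry and velocity protocol
kind: unmyelinated
D_um: 10.0
dx_um: 20.0
n_comp: 301
Rax_ohm_cm: 100.0
stimulus:
  site: 50
  amplitude_nA: 10.0
  duration_ms: 1.0
velocity_nodes: [100, 200]
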