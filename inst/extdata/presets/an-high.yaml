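# High-frequency (basal) auditory-nerve fiber: larger leak density and
# longer internodes than the low-frequency fiber; otherwise identical.
model: beif
GL: 0.4
VT: -50.0
kind: myelinated
D_um: 2.5
Ln_um: 2.0
Li_um: 450.0
n_nodes: 40
Rax_ohm_cm: 100.0
stimulus:
  site: 1
  amplitude_nA: 0.06
  duration_ms: 1.0
velocity_nodes: [10, 30]
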