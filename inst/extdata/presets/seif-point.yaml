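# Standard exponential integrate-and-fire single-compartment membrane
model: seif
Cm: 1.0
GL: 0.1
EL: -65.3
VT: -60.2
KT: 3.5
Vspike: 15.0
Vreset: -65.3
tau_ref: 2.8
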