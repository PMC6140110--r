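# Bounded exponential integrate-and-fire single-compartment membrane
model: beif
Cm: 1.0
GL: 0.1
EL: -65.3
VT: -60.2
KT: 3.5
AT: 520.0
Vrep: 10.0
tau_rep: 0.6
Arep: 90.0
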