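# Wang-Buzsaki single-compartment membrane (densities: uF/cm^2, mS/cm^2, mV)
model: wb
Cm: 1.0
GL: 0.1
GK: 15.0
GNa: 35.0
EL: -65.0
EK: -90.0
ENa: 55.0
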