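dimension,level,decrement
MO,2,0.04
MO,3,0.07
MO,4,0.16
MO,5,0.23
SC,2,0.04
SC,3,0.08
SC,4,0.17
SC,5,0.25
UA,2,0.03
UA,3,0.06
UA,4,0.15
UA,5,0.22
PD,2,0.05
PD,3,0.09
PD,4,0.20
PD,5,0.29
AD,2,0.06
AD,3,0.11
AD,4,0.23
AD,5,0.30
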