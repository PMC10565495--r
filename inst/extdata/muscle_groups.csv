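group,fascicles,wrapped_lumbar,wrapped_thoracic,pcsa_total_cm2
QL,18,0,0,16
PM,11,0,0,30
MF,25,1,0,40
IT,8,7,0,20
IL,4,4,0,14
LT,21,2,5,38
LL,5,1,0,12
RA,1,0,0,8
IO,6,0,0,30
EO,6,0,0,32
LD,14,3,14,24
TA,10,0,0,30
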