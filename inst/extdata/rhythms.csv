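rhythm,L1L2,L2L3,L3L4,L4L5,L5S1,note
R1,20.0,20.0,20.0,20.0,20.0,proportionally equal contributions
R2,16.0,21.0,24.0,23.0,16.0,synthetic stand-in; averaged 10-30 deg ROM shape
R3,19.0,22.0,24.0,21.0,14.0,synthetic stand-in; reported percentage shape
R4,24.7,24.7,24.2,17.0,9.4,synthetic stand-in; 30-100% ROM flexion with L1L2 = L2L3
R5,23.4,29.3,25.9,16.0,5.4,mean segment contributions 30-85% ROM flexion; L1L2 = 80% L2L3
R6,21.0,26.0,24.0,18.0,11.0,synthetic stand-in; return-phase shape with L1L2 = 80% L2L3
R7,22.0,27.5,24.5,16.5,9.5,synthetic stand-in; 30-10 deg return shape with L1L2 = 80% L2L3
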