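component,fap_BW,group1_mean,group1_ci,group2_mean,group2_ci
lateral_um,0,7,4,5,8
lateral_um,0.3,17,10,9,13
lateral_um,0.6,62,18,20,14
anterior_um,0,-2,7,0,2
anterior_um,0.3,7,7,10,20
anterior_um,0.6,39,26,19,16
distal_um,0,50,28,63,43
distal_um,0.3,100,52,103,67
distal_um,0.6,385,147,191,123
sagittal_mdeg,0,12,7,5,5
sagittal_mdeg,0.3,30,13,14,7
sagittal_mdeg,0.6,-8,24,32,22
frontal_mdeg,0,15,6,-2,5
frontal_mdeg,0.3,34,16,-10,16
frontal_mdeg,0.6,25,56,-14,19
transverse_mdeg,0,34,53,43,55
transverse_mdeg,0.3,-19,144,175,89
transverse_mdeg,0.6,-1175,567,359,172
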