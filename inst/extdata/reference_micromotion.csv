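component,fap_BW,group1_mean,group1_ci,group2_mean,group2_ci
lateral_um,0,7,5,2,2
lateral_um,0.3,10,4,2,3
lateral_um,0.6,16,5,2,2
anterior_um,0,4,5,0,4
anterior_um,0.3,7,9,-4,16
anterior_um,0.6,25,8,-1,19
distal_um,0,11,6,9,3
distal_um,0.3,12,6,9,3
distal_um,0.6,16,7,8,2
sagittal_mdeg,0,0,1,3,5
sagittal_mdeg,0.3,5,5,3,6
sagittal_mdeg,0.6,11,9,1,5
frontal_mdeg,0,14,6,10,12
frontal_mdeg,0.3,20,6,12,16
frontal_mdeg,0.6,35,11,10,12
transverse_mdeg,0,0,2,-1,2
transverse_mdeg,0.3,-6,14,9,16
transverse_mdeg,0.6,-61,16,14,37
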