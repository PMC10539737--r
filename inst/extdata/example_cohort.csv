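subject_id,timepoint,sofas,age,ideation,depression
S001,0,65,17,true,full-threshold
S001,1,72,17,false,subthreshold
S001,2,80,18,false,none
S002,0,75,20,false,none
S002,1,71,20,false,subthreshold
S003,0,55,16,true,full-threshold
S003,2,60,17,true,full-threshold
S004,0,68,19,,full-threshold
S004,1,74,19,false,subthreshold
S005,0,82,22,false,none
S005,1,,22,false,none
S005,2,85,23,false,none
S006,1,66,15,true,subthreshold
S006,2,70,15,true,full-threshold
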