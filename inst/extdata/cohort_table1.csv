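variable,level,AA,CA
age_group,40s,3,3
age_group,50s,14,3
age_group,60s,8,15
age_group,70s,1,4
psa_group,1,4,4
psa_group,2,14,12
psa_group,3,8,9
gleason,6,9,5
gleason,7,12,7
gleason,8,0,5
gleason,9-10,5,8
grade_group,low,21,12
grade_group,high,5,13
bcr,no,21,13
bcr,yes,5,12
metastasis,no,26,17
metastasis,yes,0,8
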