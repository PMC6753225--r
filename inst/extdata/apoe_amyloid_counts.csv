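study,apoe4,age_group,n_negative,n_positive
ADNI2,0,<70,81,18
ADNI2,0,70-80,102,40
ADNI2,0,81-90,21,18
ADNI2,1,<70,33,32
ADNI2,1,70-80,20,39
ADNI2,1,81-90,2,11
ADNI2,2,<70,4,7
ADNI2,2,70-80,1,3
ADNI2,2,81-90,0,4
AIBL,0,<70,34,4
AIBL,0,70-80,52,15
AIBL,0,81-90,15,10
AIBL,1,<70,11,6
AIBL,1,70-80,6,18
AIBL,1,81-90,2,11
AIBL,2,<70,0,1
AIBL,2,70-80,0,5
AIBL,2,81-90,0,3
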