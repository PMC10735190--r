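subject_id,X
S01,9.7
S02,29.35
S03,12.88
S04,31
S05,8.6
S06,20.71
S07,4.35
S08,13.38
S09,18.24
S10,7
S11,1
S12,26
S13,26.36
S14,34
S15,9
S16,22.18
S17,11.59
S18,28.7
S19,20
S20,7.06
S21,15.41
S22,1
S23,4.47
S24,27.47
S25,14.76
S26,30.53
S27,13.59
S28,34.59
S29,27
S30,16.59
S31,10
S32,19.88
S33,13
S34,21.47
S35,31
S36,12.18
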