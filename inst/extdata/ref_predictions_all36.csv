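subject_id,X,group,pred_rest,pred_task
S01,9.7,BAD,class_1,class_2
S02,29.35,GOOD,class_1,class_2
S03,12.88,GOOD,class_1,class_1
S04,31,GOOD,class_1,class_2
S05,8.6,BAD,class_1,class_2
S06,20.71,GOOD,class_1,class_2
S07,4.35,BAD,class_1,class_2
S08,13.38,GOOD,class_2,class_2
S09,18.24,GOOD,class_1,class_2
S10,7,BAD,class_1,class_2
S11,1,BAD,class_2,class_1
S12,26,GOOD,class_2,class_2
S13,26.36,GOOD,class_1,class_1
S14,34,GOOD,class_2,class_2
S15,9,BAD,class_2,class_2
S16,22.18,GOOD,class_1,class_1
S17,11.59,GOOD,class_2,class_2
S18,28.7,GOOD,class_2,class_2
S19,20,GOOD,class_2,class_2
S20,7.06,BAD,class_1,class_2
S21,15.41,GOOD,class_2,class_2
S22,1,BAD,class_1,class_2
S23,4.47,BAD,class_1,class_2
S24,27.47,GOOD,class_2,class_2
S25,14.76,GOOD,class_2,class_2
S26,30.53,GOOD,class_1,class_1
S27,13.59,GOOD,class_2,class_2
S28,34.59,GOOD,class_1,class_2
S29,27,GOOD,class_1,class_2
S30,16.59,GOOD,class_1,class_1
S31,10,BAD,class_2,class_2
S32,19.88,GOOD,class_2,class_2
S33,13,GOOD,class_1,class_2
S34,21.47,GOOD,class_2,class_2
S35,31,GOOD,class_1,class_1
S36,12.18,GOOD,class_1,class_2
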