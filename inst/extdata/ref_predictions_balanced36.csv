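subject_id,X,pred_rest,pred_task
S01,9.7,class_1,class_2
S02,29.35,class_1,class_2
S03,12.88,class_1,class_2
S04,31,class_1,class_2
S05,8.6,class_1,class_2
S06,20.71,class_1,class_2
S07,4.35,class_1,class_2
S08,13.38,class_1,class_2
S09,18.24,class_1,class_2
S10,7,class_1,class_2
S11,1,class_1,class_2
S12,26,class_1,class_2
S13,26.36,class_1,class_2
S14,34,class_1,class_2
S15,9,class_1,class_2
S16,22.18,class_1,class_2
S17,11.59,class_1,class_2
S18,28.7,class_1,class_2
S19,20,class_1,class_2
S20,7.06,class_1,class_2
S21,15.41,class_1,class_2
S22,1,class_1,class_2
S23,4.47,class_1,class_2
S24,27.47,class_1,class_2
S25,14.76,class_2,class_2
S26,30.53,class_1,class_1
S27,13.59,class_1,class_2
S28,34.59,class_1,class_2
S29,27,class_1,class_2
S30,16.59,class_1,class_1
S31,10,class_1,class_2
S32,19.88,class_1,class_1
S33,13,class_1,class_2
S34,21.47,class_2,class_2
S35,31,class_1,class_2
S36,12.18,class_1,class_2
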