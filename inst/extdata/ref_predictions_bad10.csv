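subject_id,X,pred_rest,pred_task
S01,9.7,class_1,class_2
S05,8.6,class_1,class_2
S07,4.35,class_1,class_2
S10,7,class_1,class_2
S11,1,class_2,class_1
S15,9,class_2,class_2
S20,7.06,class_1,class_2
S22,1,class_1,class_2
S23,4.47,class_1,class_2
S31,10,class_2,class_2
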