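subject_id,X,pred_rest,pred_task
S32,29.35,class_2,class_2
S19,12.88,class_1,class_2
S06,31,class_2,class_2
S34,20.71,class_2,class_1
S16,13.38,class_2,class_1
S12,18.24,class_2,class_2
S13,26,class_2,class_2
S29,26.36,class_2,class_2
S24,27.47,class_1,class_1
S18,28.7,class_1,class_2
S02,29.35,class_1,class_2
S26,30.53,class_2,class_1
S04,31,class_2,class_2
S35,31,class_1,class_2
S14,34,class_2,class_2
S28,34.59,class_2,class_2
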