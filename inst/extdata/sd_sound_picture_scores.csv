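subject_id,group,animal_correct,tool_correct
case_1,SD,9,10
case_2,SD,12,17
case_3,SD,14,14
case_4,SD,23,20
case_5,SD,12,8
case_6,SD,10,10
case_7,SD,4,6
case_8,SD,7,3
case_9,SD,0,0
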