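patient_id,C11,C12,C13,C14,C15,C21,C22,C23,C24,C25,C31,C32,C33,C34
A,9,8,8,2,1,6,5,4,6,7,8,8,9,6
B,2,7,8,2,1,4,3,4,5,7,5,8,7,5
C,7,6,2,2,1,5,2,3,2,4,7,5,5,5
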