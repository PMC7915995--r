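id,weight_percent
C11,4.92
C12,6.00
C13,5.83
C14,5.80
C15,4.98
C21,6.45
C22,6.46
C23,6.06
C24,6.34
C25,5.99
C31,10.05
C32,10.04
C33,10.59
C34,10.48
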