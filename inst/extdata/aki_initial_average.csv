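id,C11,C12,C13,C14,C15,C21,C22,C23,C24,C25,C31,C32,C33,C34
C11,0.00,4.00,3.00,3.00,2.00,3.00,3.00,3.00,2.00,2.00,3.00,3.00,3.00,2.00
C12,2.00,0.00,1.00,2.00,1.00,4.00,4.00,2.00,3.00,3.00,2.00,2.00,2.00,2.00
C13,2.00,2.00,0.00,2.00,2.00,2.00,2.00,1.00,2.00,1.00,4.00,3.00,3.50,3.00
C14,2.00,2.00,4.00,0.00,2.50,3.00,3.00,4.00,3.00,3.00,4.00,3.50,4.00,4.00
C15,2.00,1.00,2.00,4.00,0.00,3.00,3.00,3.00,4.00,2.00,4.00,4.00,4.00,4.00
C21,1.00,2.50,1.00,1.00,1.00,0.00,4.00,4.00,3.00,4.00,3.50,3.50,4.00,4.00
C22,1.00,2.50,2.00,3.00,1.50,4.00,0.00,4.00,3.50,4.00,4.00,3.50,4.00,4.00
C23,1.00,1.50,1.00,1.00,1.00,2.00,2.00,0.00,3.00,1.00,3.00,3.00,3.00,2.50
C24,1.00,1.00,1.00,1.00,2.00,1.00,1.00,1.00,0.00,2.00,3.00,3.50,3.00,4.00
C25,1.00,3.00,1.00,1.00,1.00,3.00,3.00,1.00,1.00,0.00,2.00,1.00,2.00,2.00
C31,4.00,4.00,4.00,3.50,4.00,2.00,2.00,2.00,2.00,2.00,0.00,4.00,4.00,4.00
C32,2.00,2.00,2.00,2.00,1.50,2.00,2.00,2.00,2.00,2.00,2.00,0.00,4.00,4.00
C33,2.00,2.00,4.00,3.00,2.00,2.00,2.00,2.00,2.00,2.00,4.00,4.00,0.00,4.00
C34,3.00,3.00,3.00,3.00,3.00,3.00,3.00,3.00,3.00,3.00,4.00,4.00,4.00,0.00
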