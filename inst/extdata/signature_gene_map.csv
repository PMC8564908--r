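probe,symbol
GJA1,GJA1
CAV1,CAV1
AXL,AXL
FN1,FN1
TMEM173,TMEM173
SOX2,SOX2
BRD4,BRD4
CLDN7,CLDN7
PAR,
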