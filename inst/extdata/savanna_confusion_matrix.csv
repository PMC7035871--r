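class,CDW,ODW,CG,DG,AG,BU,CCW,BA,W
CDW,49,3,0,2,3,0,0,0,0
ODW,0,45,0,5,2,0,2,0,0
CG,0,0,48,5,0,2,0,0,0
DG,0,2,2,38,0,7,0,0,0
AG,1,0,0,0,25,0,0,0,0
BU,0,0,0,0,0,40,0,1,0
CCW,0,0,0,0,0,0,28,0,0
BA,0,0,0,0,0,0,0,49,0
W,0,0,0,0,0,1,0,0,50
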