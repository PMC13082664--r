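"",LR,LS,PSw,Sw
LR,95.67,0.94,0.14,3.25
LS,5.31,93.16,1.28,0.24
PSw,1.37,1.18,94.41,3.04
Sw,2.08,0.8,5.28,91.84
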