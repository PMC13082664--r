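"",LR,LS,PSw,Sw
LR,95.28,0.91,0.8,3.02
LS,3.5,94.76,1.56,0.18
PSw,0.16,0.89,97.83,1.12
Sw,2.69,0.57,4.37,92.37
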