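"",LR,LS,PSw,Sw
LR,94.54,1.38,0.79,3.3
LS,3.64,94.93,0.99,0.43
PSw,0.42,2.13,92.87,4.58
Sw,2.16,0.47,2.3,95.07
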