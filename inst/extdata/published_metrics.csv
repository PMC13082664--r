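model,acc,pr,rc,f1
cnn,93.09,89.11,93.77,91.08
hybrid,94.25,90.61,95.06,92.52
transformer,94.70,91.86,94.35,92.99
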