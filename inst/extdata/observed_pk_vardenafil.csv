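"parameter","dose","value"
"cmax",10,7.2
"tmax",10,0.95
"auc0inf",10,27.29
"cmax",20,16.3
"tmax",20,0.78
"auc0inf",20,41.86
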