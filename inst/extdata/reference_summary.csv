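row,dataset,acc,sn,sp
pipeline,DRIVE,0.961,0.746,0.980
pipeline,STARE,0.946,0.758,0.963
otsu_stage,DRIVE,0.963,0.784,0.980
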