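"individual_id","sweep1","sweep2"
"sol0003",1,0
"sol0005",1,0
"sol0007",0,1
"sol0008",0,1
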