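"group_id","sweep1","sweep2"
"grp0001",1,1
"grp0002",1,1
"grp0003",1,0
"grp0004",1,0
"grp0005",1,1
"grp0006",1,1
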