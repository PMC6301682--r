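"individual_id","group_id","sweep1_site1","sweep1_site2","sweep1_site3","sweep2_site1","sweep2_site2","sweep2_site3","sweep1","sweep2"
"ind00001","grp0001",1,1,0,1,0,1,2,2
"ind00002","grp0001",0,1,1,0,1,1,2,2
"ind00003","grp0001",1,0,1,1,1,0,2,2
"ind00004","grp0001",1,0,1,0,0,0,2,0
"ind00005","grp0001",1,0,1,0,1,1,2,2
"ind00006","grp0001",1,0,1,1,1,1,2,3
"ind00007","grp0001",1,1,0,0,1,1,2,2
"ind00008","grp0001",0,0,0,1,1,1,0,3
"ind00009","grp0002",1,0,1,1,0,1,2,2
"ind00010","grp0002",0,1,1,0,0,0,2,0
"ind00011","grp0002",1,1,0,1,1,1,2,3
"ind00012","grp0002",0,0,1,0,1,1,1,2
"ind00013","grp0002",0,0,0,1,1,1,0,3
"ind00014","grp0002",0,1,1,0,0,1,2,1
"ind00015","grp0002",0,0,0,1,0,1,0,2
"ind00016","grp0003",0,1,1,0,0,0,2,0
"ind00017","grp0003",1,0,0,0,0,0,1,0
"ind00018","grp0003",0,1,0,0,0,0,1,0
"ind00019","grp0003",1,1,0,0,0,0,2,0
"ind00020","grp0004",0,1,1,0,0,0,2,0
"ind00021","grp0004",0,0,1,0,0,0,1,0
"ind00022","grp0004",1,0,1,0,0,0,2,0
"ind00023","grp0004",1,0,1,0,0,0,2,0
"ind00024","grp0004",1,0,0,0,0,0,1,0
"ind00025","grp0005",1,1,0,1,1,0,2,2
"ind00026","grp0005",0,0,1,0,1,1,1,2
"ind00027","grp0005",0,0,1,1,0,1,1,2
"ind00028","grp0005",1,1,0,1,1,0,2,2
"ind00029","grp0005",0,0,1,1,1,1,1,3
"ind00030","grp0005",0,1,1,0,1,1,2,2
"ind00031","grp0005",1,1,1,1,0,1,3,2
"ind00032","grp0006",0,1,1,1,1,1,2,3
"ind00033","grp0006",0,1,1,0,0,1,2,1
"ind00034","grp0006",1,1,1,1,1,0,3,2
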